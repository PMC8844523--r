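write_lines_tmp <- function(lines, ext = ".txt", envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = envir)
  writeLines(lines, path)
  path
}

test_that("read_ibd parses hap-IBD output, plain and gzipped", {
  fixture <- system.file("extdata", "synthetic.hapibd.ibd", package = "kinfolk")
  seg <- read_ibd(fixture, source = "hapibd")
  expect_equal(
    names(seg),
    c("id1", "id2", "chr", "start", "end", "length")
  )
  expect_gt(nrow(seg), 0)
  expect_true(all(seg$id1 <= seg$id2))
  expect_true(all(seg$start <= seg$end))
  expect_true(all(seg$length >= 0))
  # row count equals the file's line count: hap-IBD is one segment per line
  expect_equal(nrow(seg), length(readLines(fixture)))

  gz <- withr::local_tempfile(fileext = ".ibd.gz")
  con <- gzfile(gz, "w")
  writeLines(readLines(fixture), con)
  close(con)
  expect_equal(read_ibd(gz, source = "hapibd"), seg)
})

test_that("read_ibd parses ped-sim segments and doubles IBD2", {
  lines <- c(
    "a\tb\t1\t100\t5000\tIBD1\t0.0\t12.5\t12.5",
    "a\tb\t1\t6000\t9000\tIBD2\t13.0\t23.0\t10.0"
  )
  seg <- read_ibd(write_lines_tmp(lines, ".seg"), source = "pedsim")
  expect_equal(nrow(seg), 3L) # the IBD2 segment appears twice
  expect_equal(sum(seg$length == 10), 2L)
  expect_equal(sum(seg$length == 12.5), 1L)

  # doubling is what makes a fully double-shared genome reach kinship 0.5
  map <- make_map(n_chr = 1, length_cm = 50, length_bp = 1e4, n_points = 11)
  full2 <- read_ibd(
    write_lines_tmp("x\ty\t1\t1\t10000\tIBD2\t0\t50\t50", ".seg"),
    source = "pedsim"
  )
  expect_equal(ibd2kin(full2, map)$kinship, 0.5)
})

test_that("read_ibd rejects malformed segment files", {
  expect_error(read_ibd(tempfile(), source = "hapibd"), "not found")
  expect_error(
    read_ibd(write_lines_tmp("a\t1\tb\t2\t1\t100\t200"), source = "hapibd"),
    "expected 8 fields"
  )
  expect_error(
    read_ibd(
      write_lines_tmp("a\t1\tb\t2\t1\t500\t100\t1.0"),
      source = "hapibd"
    ),
    "inverted"
  )
  expect_error(
    read_ibd(
      write_lines_tmp("a\tb\t1\t100\t200\tIBD3\t0\t1\t1", ".seg"),
      source = "pedsim"
    ),
    "IBD1 or IBD2"
  )
  expect_error(
    read_ibd(write_lines_tmp("x", ".ibd"), source = "nope"),
    "arg"
  )
  expect_equal(nrow(read_ibd(write_lines_tmp(character(0)), source = "hapibd")), 0L)
})

test_that("read_map accepts 3-column and PLINK 4-column dialects identically", {
  three <- write_lines_tmp(c(
    "1 0 1000",
    "1 50 500000",
    "1 100 1000000",
    "2 0 1000",
    "2 80 800000"
  ))
  four <- write_lines_tmp(c(
    "1 rs1 0 1000",
    "1 rs2 50 500000",
    "1 rs3 100 1000000",
    "2 rs4 0 1000",
    "2 rs5 80 800000"
  ), ".map")
  m3 <- read_map(three)
  m4 <- read_map(four)
  expect_equal(m3, m4)
  expect_equal(names(m3), c("chr", "cm", "bp"))
  total <- tapply(m3$cm, m3$chr, function(x) max(x) - min(x))
  expect_equal(as.vector(total), c(100, 80))
})

test_that("read_map enforces map monotonicity", {
  bad <- write_lines_tmp(c("1 0 1000", "1 5 2000", "1 3 3000"))
  expect_error(read_map(bad), "not monotone")
  dup_bp <- write_lines_tmp(c("1 0 1000", "1 5 1000"))
  expect_error(read_map(dup_bp), "not monotone")
  expect_error(read_map(write_lines_tmp(character(0))), "empty")
})

test_that("interpolate_cm is exact at map points, linear between, clamped outside", {
  map <- read_map(write_lines_tmp(c("1 0 1", "1 100 1000001")))
  expect_equal(interpolate_cm(map, "1", 1), 0)
  expect_equal(interpolate_cm(map, "1", 1000001), 100)
  expect_equal(interpolate_cm(map, "1", 500001), 50)
  # clamping beyond the map ends
  expect_equal(interpolate_cm(map, "1", -50), 0)
  expect_equal(interpolate_cm(map, "1", 2e6), 100)
  expect_error(interpolate_cm(map, "7", 100), "absent")

  # random positions against an independent piecewise-linear evaluation
  pts <- withr::with_seed(21, {
    bp <- sort(sample(1:1e6, 12))
    cm <- cumsum(c(0, stats::runif(11, 0, 10)))
    list(bp = bp, cm = cm)
  })
  m <- read_map(write_lines_tmp(sprintf("5 %.17g %d", pts$cm, pts$bp)))
  piecewise <- function(x) {
    if (x <= pts$bp[1]) {
      return(pts$cm[1])
    }
    if (x >= pts$bp[12]) {
      return(pts$cm[12])
    }
    i <- max(which(pts$bp <= x))
    pts$cm[i] + (pts$cm[i + 1] - pts$cm[i]) * (x - pts$bp[i]) /
      (pts$bp[i + 1] - pts$bp[i])
  }
  xs <- withr::with_seed(22, sample(-1e5:1.2e6, 1000))
  expect_equal(
    interpolate_cm(m, "5", xs),
    vapply(xs, piecewise, numeric(1)),
    tolerance = 1e-9
  )
})

test_that("ibd2kin satisfies the haplotype-sharing identities", {
  map <- make_map(n_chr = 1, length_cm = 100, length_bp = 1e6, n_points = 21)
  full <- tibble::tibble(
    id1 = "a", id2 = "b", chr = "1", start = 1, end = 1e6, length = 100
  )
  # one full haplotype shared: parent-offspring-like, kinship 1/4
  expect_equal(ibd2kin(full, map)$kinship, 0.25)
  # both haplotype pairs shared everywhere: self/identical twins, 1/2
  expect_equal(ibd2kin(rbind(full, full), map)$kinship, 0.5)
})

test_that("ibd2kin is linear in shared length and additive over chromosomes", {
  map <- make_map(n_chr = 2, length_cm = 100, length_bp = 1e6, n_points = 21)
  segs <- withr::with_seed(31, {
    starts <- sort(sample(1:8e5, 6))
    tibble::tibble(
      id1 = "a", id2 = "b",
      chr = rep(c("1", "2"), each = 3),
      start = starts,
      end = starts + sample(1e4:2e5, 6)
    )
  })
  k_full <- ibd2kin(segs, map)$kinship
  k1 <- ibd2kin(segs[segs$chr == "1", ], map)$kinship
  k2 <- ibd2kin(segs[segs$chr == "2", ], map)$kinship
  expect_equal(k1 + k2, k_full)

  # halving every physical span halves the kinship (the map is linear)
  half <- dplyr::mutate(segs, end = .data$start + (.data$end - .data$start) / 2)
  expect_equal(ibd2kin(half, map)$kinship, k_full / 2)
})

test_that("ibd2kin recomputes lengths, warns on map mismatch, checks chromosomes", {
  map <- make_map(n_chr = 1, length_cm = 100, length_bp = 1e6, n_points = 21)
  seg <- tibble::tibble(
    id1 = "a", id2 = "b", chr = "1", start = 1, end = 5e5,
    length = 75 # file claims 75 cM; the map says 50
  )
  expect_warning(out <- ibd2kin(seg, map), "more than 1 cM")
  expect_equal(out$kinship, 50 / 400)

  # chromosome labels are normalized, so "chr1" matches map chromosome "1"
  seg_chr <- dplyr::mutate(seg, chr = "chr1", length = 50)
  expect_equal(ibd2kin(seg_chr, map)$kinship, 50 / 400)

  expect_error(
    ibd2kin(dplyr::mutate(seg, chr = "9"), map),
    "absent from map"
  )
  # pairs with no segments are simply absent
  expect_equal(nrow(ibd2kin(seg[0, ], map)), 0L)
})

test_that("hapibd fixture lengths agree with the map they were dropped on", {
  seg <- read_ibd(
    system.file("extdata", "synthetic.hapibd.ibd", package = "kinfolk"),
    source = "hapibd"
  )
  map <- read_map(system.file("extdata", "toy.map", package = "kinfolk"))
  expect_no_warning(kin <- ibd2kin(seg, map))
  expect_true(all(kin$kinship >= 0))
})
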