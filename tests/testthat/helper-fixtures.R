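# Shared fixtures built in code.

# The eight members of the published three-generation test family
# "testped1": a founder couple, two married children, and one grandchild per
# branch. Used wherever a hand-checkable pedigree with self, parent-offspring,
# sibling, grandparent, avuncular, and first-cousin pairs is needed.
testped1_rows <- function() {
  tibble::tibble(
    fid = "testped1",
    id = c(
      "testped1_g1-b1-s1", "testped1_g1-b1-i1",
      "testped1_g2-b1-s1", "testped1_g2-b1-i1",
      "testped1_g2-b2-s1", "testped1_g2-b2-i1",
      "testped1_g3-b1-i1", "testped1_g3-b2-i1"
    ),
    dadid = c(
      NA, NA, NA, "testped1_g1-b1-s1", NA, "testped1_g1-b1-s1",
      "testped1_g2-b1-s1", "testped1_g2-b2-s1"
    ),
    momid = c(
      NA, NA, NA, "testped1_g1-b1-i1", NA, "testped1_g1-b1-i1",
      "testped1_g2-b1-i1", "testped1_g2-b2-i1"
    ),
    sex = c(1L, 2L, 1L, 2L, 1L, 2L, 2L, 1L),
    affected = 1L
  )
}

# A reference 288-pair confusion of true vs. degraded relationship degrees
# (predicted rows x target columns), with hand-verified marginals: 234
# correct calls, a 96-pair unrelated majority class, and a weak degree-3
# class. Expanding it to label pairs gives a deterministic benchmark input.
reference_confusion_table <- function() {
  matrix(
    c(
      48, 4, 2, 1, 1,
      5, 58, 4, 0, 3,
      0, 3, 40, 1, 4,
      8, 4, 0, 6, 6,
      3, 3, 2, 0, 82
    ),
    nrow = 5, byrow = TRUE,
    dimnames = list(
      Predicted = c("0", "1", "2", "3", "unrelated"),
      Target = c("0", "1", "2", "3", "unrelated")
    )
  )
}

# expand a contingency table into its individual (target, predicted) pairs
expand_confusion_table <- function(tab) {
  df <- as.data.frame(as.table(tab), stringsAsFactors = FALSE)
  list(
    target = rep(df$Target, df$Freq),
    predicted = rep(df$Predicted, df$Freq)
  )
}

# write .fam records to a temp file, return the path
local_fam_file <- function(fam, envir = parent.frame(), gz = FALSE) {
  path <- withr::local_tempfile(
    fileext = if (gz) ".fam.gz" else ".fam",
    .local_envir = envir
  )
  write_fam(fam, path)
  path
}

# four-member nuclear family: founder couple plus two full siblings
fullsib_pedigree <- function() {
  build_pedigree(
    tibble::tibble(
      id = c("dad", "mom", "sib1", "sib2"),
      dadid = c(NA, NA, "dad", "dad"),
      momid = c(NA, NA, "mom", "mom"),
      sex = c(1L, 2L, 1L, 2L),
      affected = 1L
    ),
    fid = "nuclear"
  )
}

# Exhaustive transmission oracle for expected kinship: enumerates every
# combination of parental-allele choices down the pedigree (4 options per
# non-founder) and averages the allele-IBD indicator over all patterns.
# Independent of the recursion in kinship_matrix().
enumerate_kinship <- function(ped) {
  m <- ped$members
  n <- nrow(m)
  idx <- stats::setNames(seq_len(n), m$id)
  dad <- unname(idx[m$dadid])
  mom <- unname(idx[m$momid])
  nonf <- which(!is.na(dad))
  n_pat <- 4^length(nonf)
  phi <- matrix(0, n, n, dimnames = list(m$id, m$id))
  for (pat in seq_len(n_pat) - 1L) {
    a1 <- integer(n)
    a2 <- integer(n)
    lab <- 0L
    code <- pat
    for (i in seq_len(n)) {
      if (is.na(dad[i])) {
        a1[i] <- lab + 1L
        a2[i] <- lab + 2L
        lab <- lab + 2L
      } else {
        choice <- code %% 4L
        code <- code %/% 4L
        a1[i] <- if (choice %% 2L == 0L) a1[dad[i]] else a2[dad[i]]
        a2[i] <- if (choice %/% 2L == 0L) a1[mom[i]] else a2[mom[i]]
      }
    }
    for (i in seq_len(n)) {
      for (j in i:n) {
        s <- ((a1[i] == a1[j]) + (a1[i] == a2[j]) +
          (a2[i] == a1[j]) + (a2[i] == a2[j])) / 4
        phi[i, j] <- phi[i, j] + s
        if (j > i) phi[j, i] <- phi[j, i] + s
      }
    }
  }
  phi / n_pat
}
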