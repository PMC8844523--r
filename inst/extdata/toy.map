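1 0 1
1 2 2000001
1 4 4000001
1 6 6000001
1 8 8000001
1 10 10000001
1 12 12000001
1 14 14000001
1 16 16000001
1 18 18000001
1 20 20000001
1 22 22000001
1 24 24000001
1 26 26000001
1 28 28000001
1 30 30000001
1 32 32000001
1 34 34000001
1 36 36000001
1 38 38000001
1 40 40000001
1 42 42000001
1 44 44000001
1 46 46000001
1 48 48000001
1 50 50000000
1 52 52000000
1 54 54000000
1 56 56000000
1 58 58000000
1 60 60000000
1 62 62000000
1 64 64000000
1 66 66000000
1 68 68000000
1 70 70000000
1 72 72000000
1 74 74000000
1 76 76000000
1 78 78000000
1 80 80000000
1 82 82000000
1 84 84000000
1 86 86000000
1 88 88000000
1 90 90000000
1 92 92000000
1 94 94000000
1 96 96000000
1 98 98000000
1 100 100000000
2 0 1
2 2 2000001
2 4 4000001
2 6 6000001
2 8 8000001
2 10 10000001
2 12 12000001
2 14 14000001
2 16 16000001
2 18 18000001
2 20 20000001
2 22 22000001
2 24 24000001
2 26 26000001
2 28 28000001
2 30 30000001
2 32 32000001
2 34 34000001
2 36 36000001
2 38 38000001
2 40 40000001
2 42 42000001
2 44 44000001
2 46 46000001
2 48 48000001
2 50 50000000
2 52 52000000
2 54 54000000
2 56 56000000
2 58 58000000
2 60 60000000
2 62 62000000
2 64 64000000
2 66 66000000
2 68 68000000
2 70 70000000
2 72 72000000
2 74 74000000
2 76 76000000
2 78 78000000
2 80 80000000
2 82 82000000
2 84 84000000
2 86 86000000
2 88 88000000
2 90 90000000
2 92 92000000
2 94 94000000
2 96 96000000
2 98 98000000
2 100 100000000
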