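Place the replicate-averaged, DESeq2-normalized 27-condition expression
matrix distributed with the study (genes x conditions CSV, gene IDs in the
first column) here as study_matrix.csv to enable the full published-number
reproduction check in tests/testthat/test-acceptance.R. The file is not
redistributable with this package.
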