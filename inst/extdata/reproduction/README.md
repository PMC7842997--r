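# Reproduction datasets

The published microarray datasets used by the reproduction blocks at the
end of `tests/testthat/test-acceptance.R` are not redistributable with
this package. To run those checks, place the files here before
installing:

- `leukemia.csv` — curated leukemia matrix (3051 genes x 72 samples),
  samples as rows, class label in the last column
- `colon.csv` — curated colon cancer matrix (2000 genes x 62 samples,
  classes 22:40), same layout
- `GDS4431.soft` — the full-SOFT autism GDS file from GEO
  (54675 probes x 146 samples)
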