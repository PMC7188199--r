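# Default analysis configuration.
# threshold: difficulty boundary on operative time, minutes (>= is difficult)
threshold: 210
covariance: pooled      # pooled within-group | total (all vectors combined)
n_boot: 200             # .632 bootstrap replicates
min_group: 2            # minimum per-class count in a valid resample
cv_band: 1.6            # stage-2 LOOCV band, percentage points
ridge: 0                # diagonal ridge for near-singular covariances

# canonical name -> source column header (only needed when the source file
# uses neither the canonical snake_case names nor the published aliases)
aliases: {}

# modified Clavien grade -> ordinal rank used in rank correlations
clavien_ranks:
  "0": 0
  "1": 1
  "2a": 2
  "2b": 3
  "3a": 4
  "3b": 5
  "4": 6
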