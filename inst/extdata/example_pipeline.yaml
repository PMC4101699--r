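# Annotated pipeline configuration.
#
# Either simulate a cohort (data: scenario) or point at your own files
# (data: expression / clinical / schema). All randomness derives from
# `seed`; rerunning the same configuration reproduces every artifact
# byte for byte.

seed: 7

data:
  # one of the frozen scenarios: null | strong_core | core_plus_trait | full_scale
  scenario: core_plus_trait
  # ... or real inputs instead:
  # expression: expression.tsv      # genes x subjects, log2 scale
  # dialect: tsv                    # tsv | gct
  # clinical: clinical.csv          # subject_id + characteristics
  # schema: clinical.schema.yaml    # column -> continuous|binary|ordinal

vista:
  n_runs: 30            # independent restarts (full-scale design: 500)
  reservoir_size: 12    # subjects parked outside the comparison (full scale: 40)
  max_attempts: 200     # attempted swaps per run (full scale: 2000)
  engine: ttest         # sam | ttest; sam is the reference objective
  fdr_threshold: 0.1    # permissive objective cutoff easing seed-group emergence
  n_permutations: 100   # SAM permutations inside the optimizer

assoc:
  alpha: 0.05           # per-trait significance threshold (inclusive)

cooccurrence:
  max_order: 3          # report pairs and triplets
  baseline_divisions: 2000   # random divisions (full-scale design: 10000)

# optional downstream stage
subtypes:
  fdr_threshold: 0.05   # stricter reporting cutoff for subtype DE
  min_fc: 2             # fold-change threshold (inclusive) for gene lists
  definitions:
    - name: "Severity high vs low"
      a_rule: "SEVERITY >= 4"
      b_rule: "SEVERITY <= 2"
      distinctive_trait: SEVERITY

out_dir: vista_out
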