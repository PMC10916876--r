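# Term-registry JSON schema (version 1.0)

A registry file is one JSON object:

```json
{
  "schema_version": "1.0",
  "provenance": {
    "created": "2026-09-22T00:00:00+0000",
    "seed": 11,
    "selection": { "max_iter": 100, "alpha": 0.05, "...": "..." },
    "r2_threshold": 0.25,
    "mcc_threshold": 0.5,
    "profiles_digest": "xxh...",
    "readouts_digest": "xxh..."
  },
  "feature_universe": ["f001", "f002", "..."],
  "terms": [
    {
      "term_id": "viability_intensity_readout_01_process_01",
      "level1_assay": "viability",
      "level2_measurement": "intensity",
      "level3_phenotype": "readout_01",
      "level4_process": "process_01",
      "level5_features": ["f006", "f030", "..."],
      "regression_gate": {
        "metric_name": "r_squared", "value": 0.978, "passed": true,
        "split_seed": 1, "threshold": 0.25
      },
      "classifier_gate": {
        "metric_name": "mcc", "value": 1.0, "passed": true,
        "split_seed": 2, "threshold": 0.5
      }
    }
  ]
}
```

Rules enforced on read:

* `schema_version` must equal `"1.0"`; anything else is an error.
* `term_id` values must be unique.
* every `level5_features` entry must be non-empty and a subset of
  `feature_universe`.
* gate blocks may be `null` (user-authored registries); when present,
  `passed` is recomputed as `value > threshold` (strict).

Terms are written sorted by `term_id`, so identical registries serialize
to identical bytes.
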