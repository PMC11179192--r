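{
  "version": "1",
  "route_tag": "3ss_nonAG",
  "feature_names": ["distance_to_site", "conservation", "cons_imputed", "py_tract_ref", "delta_py_tract", "py_run_ref", "delta_py_run", "u2_mfe_ref", "delta_u2_mfe", "fold_dG_ref", "delta_fold_dG", "openness_ref", "delta_openness", "site_strength_ref", "delta_site_strength", "novel_ag_flag", "novel_ag_to_canonical_dist"],
  "beta0": 0,
  "beta": [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
  "center": [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
  "scale": [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1],
  "lambda": 0,
  "cutoff": 0.07784796,
  "trained": false,
  "metadata": {
    "note": "untrained placeholder carrying the published decision cutoff"
  }
}
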