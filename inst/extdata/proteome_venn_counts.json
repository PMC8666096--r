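{
  "comment": "Published region counts of the three-group plasma proteome comparison. scd_total counts proteins detected in either sickle-cell group; regions not printed individually (SCD proteins shared with controls) are reconstructed as a single triple-overlap region of scd_total minus the three printed SCD regions.",
  "pos_only": 289,
  "neg_only": 335,
  "pos_neg": 148,
  "control_only": 239,
  "scd_total": 1172
}
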