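{
  "title": "wgdkit pipeline report",
  "required": {
    "config": "object",
    "seed": "number",
    "n_genes": "array",
    "duplicate_classes": "object",
    "n_blocks_self": "number",
    "paralog_ks": "object",
    "wgd_age_my": "number",
    "calibration": "object",
    "ortholog_ks": "object",
    "shared_wgd": "string",
    "telomere_status": "object",
    "syntenic_modal_depth": "number",
    "syntenic_modal_depth_control": "number",
    "fractionation": "object",
    "retention_totals": "object"
  }
}
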