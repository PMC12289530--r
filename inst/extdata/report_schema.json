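{
  "required": ["seed", "config_hash", "stages", "dep_counts",
               "nascent_counts", "candidates"],
  "stage_required": ["input", "removed", "retained"],
  "nonconserving_stages": []
}
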