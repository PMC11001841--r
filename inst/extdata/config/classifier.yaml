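# Series-classification rule configuration.
# Keyword lists are case-insensitive regular expressions matched against the
# free-text series description (0008,103E) and sequence name (0018,0024);
# thresholds are documented defaults, re-curatable without touching code.
diffusion_keywords: ["dwi", "diffusion", "\\badc\\b", "\\bdif\\b", "trace"]
t1_keywords: ["t1"]
t2_keywords: ["t2", "stir"]
dce_keywords: ["dce", "dyn", "vibrant", "subtract"]
dce_flip_angle_max_deg: 20
obliquity_threshold: 0.8
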