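{"title": "difference map artifact", "required": ["nodes", "arcs", "criterion", "palette_id"]}
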