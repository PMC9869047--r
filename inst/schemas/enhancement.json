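{"title": "enhancement map artifact", "required": ["nodes", "arcs", "palette_id"]}
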