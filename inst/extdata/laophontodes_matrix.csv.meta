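char_id,taxon
4,macclintocki
5,macclintocki
17,spongiosus
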