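constructs_synthetic.yaml: example construct-definition file for
read_constructs_yaml(). Segment architectures carry the published domain
boundaries of the LCD2-CTPR variants, but the sequences are synthetic
placeholders of the correct lengths (see ?lcd2_ctpr_spec), not published
sequences.
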