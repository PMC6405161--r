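R001
R002
R003
R004
R005
R006
R007
R008
R009
R010
R011
R012
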