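PIGA
PIGB
PIGC
PIGF
PIGG
PIGH
PIGK
PIGL
PIGM
PIGN
PIGO
PIGP
PIGQ
PIGS
PIGT
PIGU
PIGV
PIGW
PIGX
PIGY
PIGZ
GPAA1
PGAP1
PGAP2
PGAP3
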