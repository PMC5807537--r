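# Vinculin domain partition (inclusive residue ranges). D1-D4 form the
# head (Vh); Vt is the tail five-helix bundle. The metavinculin insert
# shifts tail numbering by +68 (insert after residue 915).
D1: [1, 252]
D2: [253, 485]
D3: [486, 717]
D4: [718, 836]
hinge: [837, 895]
Vt: [896, 1066]
insert: [916, 983]
tail_offset_metavinculin: 68
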