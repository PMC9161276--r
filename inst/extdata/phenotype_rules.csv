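subset,positive,negative
CD4_T,CD3;CD4,
CD8_T,CD3,CD4
B_cell,CD20,
FDC,CD21,
CD3_TRM,CD3;CD103,
CD4_TRM,CD3;CD4;CD103,
CD8_TRM,CD3;CD103,CD4
GC_B,CD20;BCL6,
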