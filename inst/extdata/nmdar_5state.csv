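parameter,value,units,description
kon,5,per_mM_per_ms,glutamate binding rate for both binding steps (U->C1 and C1->C2)
koff,0.0129,per_ms,glutamate unbinding rate for both steps (C1->U and C2->C1)
kd,0.0084,per_ms,desensitisation rate (C2->D)
kr,0.0068,per_ms,resensitisation rate (D->C2)
ko,0.0465,per_ms,channel opening rate (C2->O)
kc,0.0738,per_ms,channel closing rate (O->C2)
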