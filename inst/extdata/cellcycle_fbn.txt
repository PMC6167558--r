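Fundamental Boolean Network with 10 genes
Genes involved:
CycD, Rb, E2F, CycE, CycA, p27, Cdc20, Cdh1, UbcH10, CycB
Multiple Transition Functions for CycD with decay value = 1:
CycD_1_Activator: CycD = CycD (Confidence: 1, TimeStep: 1)
CycD_2_Inhibitor: CycD = !CycD (Confidence: 1, TimeStep: 1)
Multiple Transition Functions for Rb with decay value = 1:
Rb_1_Activator: Rb = !CycD&p27&!CycB (Confidence: 1, TimeStep: 1)
Rb_2_Activator: Rb = !CycD&!CycE&!CycB&!CycA (Confidence: 1, TimeStep: 1)
Rb_3_Inhibitor: Rb = CycD (Confidence: 1, TimeStep: 1)
Rb_4_Inhibitor: Rb = CycB (Confidence: 1, TimeStep: 1)
Rb_5_Inhibitor: Rb = CycA&!p27 (Confidence: 1, TimeStep: 1)
Rb_6_Inhibitor: Rb = CycE&!p27 (Confidence: 1, TimeStep: 1)
Multiple Transition Functions for E2F with decay value = 1:
E2F_1_Activator: E2F = !Rb&!CycA&!CycB (Confidence: 1, TimeStep: 1)
E2F_2_Activator: E2F = !Rb&p27&!CycB (Confidence: 1, TimeStep: 1)
E2F_3_Inhibitor: E2F = Rb (Confidence: 1, TimeStep: 1)
E2F_4_Inhibitor: E2F = CycB (Confidence: 1, TimeStep: 1)
E2F_5_Inhibitor: E2F = CycA&!p27 (Confidence: 1, TimeStep: 1)
Multiple Transition Functions for CycE with decay value = 1:
CycE_1_Activator: CycE = !Rb&E2F (Confidence: 1, TimeStep: 1)
CycE_2_Inhibitor: CycE = !E2F (Confidence: 1, TimeStep: 1)
CycE_3_Inhibitor: CycE = Rb (Confidence: 1, TimeStep: 1)
Multiple Transition Functions for CycA with decay value = 1:
CycA_1_Activator: CycA = !Rb&E2F&!Cdc20&!UbcH10 (Confidence: 1, TimeStep: 1)
CycA_2_Activator: CycA = !Rb&CycA&!Cdc20&!UbcH10 (Confidence: 1, TimeStep: 1)
CycA_3_Activator: CycA = !Rb&CycA&!Cdc20&!Cdh1 (Confidence: 1, TimeStep: 1)
CycA_4_Activator: CycA = !Rb&E2F&!Cdc20&!Cdh1 (Confidence: 1, TimeStep: 1)
CycA_5_Inhibitor: CycA = Rb (Confidence: 1, TimeStep: 1)
CycA_6_Inhibitor: CycA = Cdc20 (Confidence: 1, TimeStep: 1)
CycA_7_Inhibitor: CycA = !E2F&!CycA (Confidence: 1, TimeStep: 1)
CycA_8_Inhibitor: CycA = Cdh1&UbcH10 (Confidence: 1, TimeStep: 1)
Multiple Transition Functions for p27 with decay value = 1:
p27_1_Activator: p27 = !CycD&!CycE&!CycB&!CycA (Confidence: 1, TimeStep: 1)
p27_2_Activator: p27 = !CycD&!CycA&!CycB&p27 (Confidence: 1, TimeStep: 1)
p27_3_Activator: p27 = !CycD&!CycE&!CycB&p27 (Confidence: 1, TimeStep: 1)
p27_4_Inhibitor: p27 = CycD (Confidence: 1, TimeStep: 1)
p27_5_Inhibitor: p27 = CycB (Confidence: 1, TimeStep: 1)
p27_6_Inhibitor: p27 = CycA&!p27 (Confidence: 1, TimeStep: 1)
p27_7_Inhibitor: p27 = CycE&!p27 (Confidence: 1, TimeStep: 1)
p27_8_Inhibitor: p27 = CycE&CycA (Confidence: 1, TimeStep: 1)
Multiple Transition Functions for Cdc20 with decay value = 1:
Cdc20_1_Activator: Cdc20 = CycB (Confidence: 1, TimeStep: 1)
Cdc20_2_Inhibitor: Cdc20 = !CycB (Confidence: 1, TimeStep: 1)
Multiple Transition Functions for Cdh1 with decay value = 1:
Cdh1_1_Activator: Cdh1 = Cdc20 (Confidence: 1, TimeStep: 1)
Cdh1_2_Activator: Cdh1 = !CycA&!CycB (Confidence: 1, TimeStep: 1)
Cdh1_3_Activator: Cdh1 = p27&!CycB (Confidence: 1, TimeStep: 1)
Cdh1_4_Inhibitor: Cdh1 = !Cdc20&CycB (Confidence: 1, TimeStep: 1)
Multiple Transition Functions for UbcH10 with decay value = 1:
UbcH10_1_Activator: UbcH10 = !Cdh1 (Confidence: 1, TimeStep: 1)
UbcH10_2_Activator: UbcH10 = Cdc20&UbcH10 (Confidence: 1, TimeStep: 1)
UbcH10_3_Activator: UbcH10 = UbcH10&CycB (Confidence: 1, TimeStep: 1)
UbcH10_4_Activator: UbcH10 = CycA&UbcH10 (Confidence: 1, TimeStep: 1)
UbcH10_5_Inhibitor: UbcH10 = Cdh1&!UbcH10 (Confidence: 1, TimeStep: 1)
Multiple Transition Functions for CycB with decay value = 1:
CycB_1_Activator: CycB = !Cdc20&!Cdh1 (Confidence: 1, TimeStep: 1)
CycB_2_Inhibitor: CycB = Cdh1 (Confidence: 1, TimeStep: 1)
CycB_3_Inhibitor: CycB = Cdc20 (Confidence: 1, TimeStep: 1)
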