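segment,node_a,node_b,length_mm,diameter_mm
LICA_seg,LICA,ICA_L,30,4.2
RICA_seg,RICA,ICA_R,30,4.2
LVA_seg,LVA,VB,25,3.2
RVA_seg,RVA,VB,25,3.2
BA,VB,BT,25,4.0
L_P1,BT,P1_L,8,2.2
R_P1,BT,P1_R,8,2.2
L_P2,P1_L,LPCA,25,2.0
R_P2,P1_R,RPCA,25,2.0
L_M1,ICA_L,LMCA,20,2.9
R_M1,ICA_R,RMCA,20,2.9
L_A1,ICA_L,A1_L,13,2.3
R_A1,ICA_R,A1_R,13,2.3
L_A2,A1_L,LACA,25,2.4
R_A2,A1_R,RACA,25,2.4
ACoA,A1_L,A1_R,3,1.5
L_PCoA,ICA_L,P1_L,15,1.4
R_PCoA,ICA_R,P1_R,15,1.4
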