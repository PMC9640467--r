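code,one_letter,smiles,molecular_weight,is_natural,chirality,logp,net_charge_ph7,isoelectric_point,hydrophobicity_group,charge_group,size_group
ALA,A,N[C@@H](C)C(=O)O,89.09,TRUE,L,0.0388000000000001,0,5.64999994188479,polar,neutral,small
ARG,R,N[C@@H](CCCNC(=N)N)C(=O)O,174.2,TRUE,L,0.4731,0.99999683773234,10.7500000369548,charged,positive,medium
ASN,N,N[C@@H](CC(N)=O)C(=O)O,132.12,TRUE,L,-0.4054,0,5.64999994188479,polar,neutral,medium
ASP,D,N[C@@H](CC(=O)O)C(=O)O,133.1,TRUE,L,-0.5064,-0.999000999000999,3.14999717182111,charged,negative,medium
CYS,C,N[C@@H](CS)C(=O)O,121.16,TRUE,L,-0.0512999999999999,-0.0477267210342038,5.2604291507299,polar,neutral,medium
GLN,Q,N[C@@H](CCC(N)=O)C(=O)O,146.15,TRUE,L,-0.0153,0,5.64999994188479,polar,neutral,medium
GLU,E,N[C@@H](CCC(=O)O)C(=O)O,147.13,TRUE,L,-0.1163,-0.999000999000999,3.14999717182111,charged,negative,medium
GLY,G,NCC(=O)O,75.07,TRUE,NA,-0.3497,0,5.64999994188479,polar,neutral,small
HIS,H,N[C@@H](Cc1c[nH]cn1)C(=O)O,155.15,TRUE,L,-0.0153,0.0909090909090909,7.50004609606075,polar,neutral,medium
ILE,I,N[C@@H]([C@@H](C)CC)C(=O)O,131.17,TRUE,L,1.065,0,5.64999994188479,hydrophobic,neutral,medium
LEU,L,N[C@@H](CC(C)C)C(=O)O,131.17,TRUE,L,1.065,0,5.64999994188479,hydrophobic,neutral,medium
LYS,K,N[C@@H](CCCCN)C(=O)O,146.19,TRUE,L,0.8482,0.99968387220237,9.75000003936641,charged,positive,medium
MET,M,N[C@@H](CCSC)C(=O)O,149.21,TRUE,L,0.772,0,5.64999994188479,polar,neutral,medium
PHE,F,N[C@@H](Cc1ccccc1)C(=O)O,165.19,TRUE,L,1.2616,0,5.64999994188479,hydrophobic,neutral,medium
PRO,P,N1CCC[C@H]1C(=O)O,115.13,TRUE,L,0.0721000000000001,0,5.64999994188479,polar,neutral,small
SER,S,N[C@@H](CO)C(=O)O,105.09,TRUE,L,-0.9888,0,5.64999994188479,polar,neutral,small
THR,T,N[C@@H]([C@H](O)C)C(=O)O,119.12,TRUE,L,-0.6003,0,5.64999994188479,polar,neutral,small
TRP,W,N[C@@H](Cc1c[nH]c2ccccc12)C(=O)O,204.23,TRUE,L,1.7429,0,5.64999994188479,hydrophobic,neutral,large
TYR,Y,N[C@@H](Cc1ccc(O)cc1)C(=O)O,181.19,TRUE,L,0.9672,-0.000999000999000999,5.62928680963592,polar,neutral,large
VAL,V,N[C@@H](C(C)C)C(=O)O,117.15,TRUE,L,0.6749,0,5.64999994188479,polar,neutral,small
ORN,NA,N[C@@H](CCCN)C(=O)O,132.16098,FALSE,L,0.4581,0.99968387220237,9.75000003936641,charged,positive,medium
MKD,NA,N[C@](C)(CCCCCC)C(=O)O,173.25266,FALSE,L,2.3794,0,5.64999994188479,hydrophobic,neutral,medium
41H,NA,N[C@](C)(Cc1ccccc1)C(=O)O,179.21572,FALSE,L,1.6517,0,5.64999994188479,hydrophobic,neutral,medium
54C,NA,N[C@@H](Cc1cn(C)c2ccccc12)C(=O)O,218.25176,FALSE,L,1.7533,0,5.64999994188479,hydrophobic,neutral,large
G5G,NA,N[C@@H](CC1CCCCC1)C(=O)O,171.23678,FALSE,L,1.9893,0,5.64999994188479,hydrophobic,neutral,medium
C1J,NA,N[C@@H](Cc1ccc(OC)cc1)C(=O)O,195.21512,FALSE,L,1.2702,0,5.64999994188479,hydrophobic,neutral,large
KHB,NA,N[C@@H](Cc1cccc2ccccc12)C(=O)O,215.24782,FALSE,L,2.4148,0,5.64999994188479,hydrophobic,neutral,large
DAB,NA,N[C@@H](CCN)C(=O)O,118.1344,FALSE,L,0.0680000000000001,0.99968387220237,9.75000003936641,charged,positive,small
AIB,NA,NC(C)(C)C(=O)O,103.11976,FALSE,NA,0.4289,0,5.64999994188479,polar,neutral,small
NLE,NA,N[C@@H](CCCC)C(=O)O,131.17292,FALSE,L,1.2091,0,5.64999994188479,hydrophobic,neutral,medium
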