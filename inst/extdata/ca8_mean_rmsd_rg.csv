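label,metric,mean,pct_diff_printed
WT,RMSD,2.507,0.00
S100A,RMSD,2.465,1.68
S100L,RMSD,2.002,20.14
S100P,RMSD,2.251,10.21
E109D,RMSD,2.222,11.37
G162R,RMSD,2.862,-14.16
R237Q,RMSD,2.248,10.33
WT,Rg,18.120,0.00
S100A,Rg,17.961,0.88
S100L,Rg,17.926,1.07
S100P,Rg,18.024,0.53
E109D,Rg,17.865,1.41
G162R,Rg,18.113,0.04
R237Q,Rg,17.944,0.97
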