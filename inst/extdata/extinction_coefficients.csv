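# Literature census of Beer's-law canopy extinction coefficients (k) for
# switchgrass cultivars across field trials and model parameterisations.
# Sign conventions of the source studies are preserved; analyses use |k|.
cultivar,k
Alamo,0.33
Alamo,0.33
CIR,-0.54
Pathfinder,-0.54
Sunburst,-0.49
Alamo,0.65
Alamo,-0.31
Kanlow,-0.23
CIR,-0.36
Summer,-0.27
Shawnee,-0.29
Kanlow x Summer,-0.28
Alamo,-0.38
Kanlow,-0.67
CIR,-1.11
Alamo,0.34
Alamo,0.47
Alamo,0.43
Alamo,0.35
Alamo,0.34
Alamo,0.34
Alamo,0.39
Alamo,0.37
Alamo,0.44
Alamo,0.41
Alamo,0.35
Alamo,0.27
Alamo,0.36
Alamo,0.33
unspecified,0.5
Alamo,0.33
Blackwell,0.33
CIR,0.36
Kanlow,0.5
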