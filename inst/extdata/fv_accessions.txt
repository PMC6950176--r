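# Versioned GenBank accessions of the 38 foamy virus isolates used for
# calibration scans (fetch with: dumbbellscan fetch --accessions this_file)
JX307862.1
JX307861.1
U94514.1
AY134750.1
AF201902.1
AJ564746.1
U85043.1
NC_039242.1
KC292054.1
U21247.1
Y07723.1
Y07724.1
Y07725.1
JQ867462.1
NC_010820.1
EU010385.1
JQ867463.1
JQ867465.1
JQ867464.1
MF582544.1
M74895.1
GU356395.1
JQ867466.1
U04327.1
HM245790.1
X54482.1
KF026286.1
LC094267.1
AB923518.1
MF280817.1
KM233624.1
NC_039085.1
AJ544579.1
KX087159
NC_001364.1
GU356394.1
KP143760.1
L25422
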