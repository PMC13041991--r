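label	roi_group
V1	visual
V2	visual
V3	visual
V4	visual
V3A	visual
V3B	visual
V4t	visual
V6	visual
V7	visual
V8	visual
MT	visual
MST	visual
LO1	visual
LO2	visual
LO3	visual
PIT	visual
FFC	visual
VVC	visual
VMV1	visual
VMV2	visual
VMV3	visual
PH	visual
A1	auditory
A4	auditory
A5	auditory
LBelt	auditory
MBelt	auditory
PBelt	auditory
RI	auditory
TA2	auditory
STGa	auditory
STSvp	audiovisual
STSdp	audiovisual
STSva	audiovisual
STSda	audiovisual
TPOJ1	audiovisual
TPOJ2	audiovisual
TPOJ3	audiovisual
STV	audiovisual
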