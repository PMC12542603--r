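symbol
HMGN1
HMGN2
HMGN3
HMGN4
HMGN5
HMGA1
HMGA2
HMGB1
HMGB2
HMGB3
HMGB4
HMGXB3
HMGXB4
HMG20A
HMG20B
SMARCA1
SMARCA2
SMARCA4
SMARCA5
SMARCAD1
SMARCAL1
SMARCB1
SMARCC1
SMARCC2
SMARCD1
SMARCD2
SMARCD3
SMARCE1
ARID1A
ARID1B
ARID2
PBRM1
BRD7
BRD9
ACTL6A
ACTL6B
BCL7A
BCL7B
BCL7C
BCL11A
BCL11B
DPF1
DPF2
DPF3
PHF10
BPTF
BAZ1A
BAZ1B
BAZ2A
BAZ2B
CECR2
RSF1
CHRAC1
POLE3
CHD1
CHD1L
CHD2
CHD3
CHD4
CHD5
CHD6
CHD7
CHD8
CHD9
INO80
INO80B
INO80C
INO80D
INO80E
RUVBL1
RUVBL2
YY1
YY1AP1
EP400
TRRAP
MTA1
MTA2
MTA3
MBD1
MBD2
MBD3
MBD4
MBD5
MBD6
MECP2
GATAD2A
GATAD2B
RBBP4
RBBP7
CDK2AP1
EP300
CREBBP
KAT2A
KAT2B
KAT5
KAT6A
KAT6B
KAT7
KAT8
KAT14
HAT1
ELP3
NCOA1
NCOA2
NCOA3
CLOCK
GTF3C4
HDAC1
HDAC2
HDAC3
HDAC4
HDAC5
HDAC6
HDAC7
HDAC8
HDAC9
HDAC10
HDAC11
SIRT1
SIRT2
SIRT3
SIRT4
SIRT5
SIRT6
SIRT7
KMT2A
KMT2B
KMT2C
KMT2D
KMT2E
KMT5A
KMT5B
KMT5C
SETD1A
SETD1B
SETD2
SETD3
SETD5
SETD6
SETD7
SETDB1
SETDB2
SETMAR
ASH1L
ASH2L
WDR5
WDR82
RBBP5
DPY30
MEN1
HCFC1
HCFC2
OGT
SUV39H1
SUV39H2
EHMT1
EHMT2
PRDM1
PRDM2
PRDM4
PRDM5
PRDM6
PRDM8
PRDM9
PRDM16
NSD1
NSD2
NSD3
DOT1L
EZH1
EZH2
SUZ12
EED
AEBP2
JARID2
PHF1
PHF19
MTF2
EPOP
PALI1
RING1
RNF2
BMI1
PCGF1
PCGF2
PCGF3
PCGF5
PCGF6
CBX1
CBX2
CBX3
CBX4
CBX5
CBX6
CBX7
CBX8
PHC1
PHC2
PHC3
SCMH1
SCML2
KDM1A
KDM1B
KDM2A
KDM2B
KDM3A
KDM3B
KDM4A
KDM4B
KDM4C
KDM4D
KDM5A
KDM5B
KDM5C
KDM6A
KDM6B
KDM7A
KDM8
JMJD1C
JMJD6
PHF2
PHF8
UTY
DNMT1
DNMT3A
DNMT3B
DNMT3L
UHRF1
UHRF2
TET1
TET2
TET3
TDG
GADD45A
GADD45B
GADD45G
ZBTB33
ZBTB4
ZBTB38
CTCF
CTCFL
RAD21
RAD21L1
SMC1A
SMC1B
SMC2
SMC3
SMC4
SMC5
SMC6
STAG1
STAG2
STAG3
NIPBL
MAU2
WAPL
PDS5A
PDS5B
ESCO1
ESCO2
NCAPD2
NCAPD3
NCAPG
NCAPG2
NCAPH
NCAPH2
NSMCE1
NSMCE2
NSMCE3
NSMCE4A
EID3
REC8
SGO1
SGO2
CDCA5
ESPL1
PTTG1
LMNA
LMNB1
LMNB2
BANF1
EMD
TMPO
TOR1AIP1
LBR
LEMD1
LEMD2
LEMD3
SUN1
SUN2
SYNE1
SYNE2
PRR14
SAFB
SAFB2
MATR3
NUMA1
NUP98
NUP153
NUP93
NUP210
TPR
AHCTF1
SENP1
SENP2
TOP1
TOP2A
TOP2B
TOP3A
TOP3B
ATRX
DAXX
HELLS
CDCA7
TTF1
TTF2
ERCC6
ERCC6L
ERCC6L2
SHPRH
HLTF
RAD54L
RAD54B
ATAD2
ATAD2B
BRD1
BRD2
BRD3
BRD4
BRDT
BRD8
TAF1
TAF3
PHIP
SP100
SP110
SP140
ASF1A
ASF1B
CHAF1A
CHAF1B
NAP1L1
NAP1L2
NAP1L3
NAP1L4
SET
ANP32A
ANP32B
ANP32E
NPM1
NPM2
NPM3
SUPT6H
SUPT16H
SSRP1
SPT2
NASP
HIRA
UBN1
UBN2
CABIN1
DEK
TSPYL1
TSPYL2
TSPYL4
APLF
ATAD5
H2AFY
H2AFY2
H2AFV
H2AFZ
H2AFX
CENPA
CENPB
CENPC
HJURP
MIS18A
MIS18BP1
OIP5
KNL1
HP1BP3
PHF6
PHF21A
PHF23
ING1
ING2
ING3
ING4
ING5
PYGO1
PYGO2
SPIN1
GLYR1
ZMYND8
ZMYND11
TRIM24
TRIM28
TRIM33
L3MBTL1
L3MBTL2
L3MBTL3
MSL1
MSL2
MSL3
KANSL1
KANSL2
KANSL3
MCRS1
PHF20
PHF20L1
MORF4L1
MORF4L2
MRGBP
EPC1
EPC2
DMAP1
VPS72
YEATS2
YEATS4
GAS41
ENY2
ATXN7
ATXN7L3
USP22
USP21
USP16
USP3
USP12
MYSM1
BAP1
ASXL1
ASXL2
ASXL3
FOXK1
FOXK2
OGA
ZNF143
ZNF274
ZNF512B
YBX1
SATB1
SATB2
SP1
MAZ
MYB
ADNP
POGZ
HNRNPK
HNRNPU
HNRNPUL1
SAF-B
MECOM
IKZF1
IKZF2
IKZF3
ARID3A
ARID3B
ARID4A
ARID4B
ARID5A
ARID5B
JADE1
JADE2
JADE3
BRPF1
BRPF3
MEAF6
SMCHD1
LRIF1
PHF13
BEND3
BAHD1
BAHCC1
MPHOSPH8
MORC1
MORC2
MORC3
MORC4
TASOR
PPHLN1
SIN3A
SIN3B
SAP18
SAP30
SAP30L
SAP130
SUDS3
FAM60A
TBL1X
TBL1XR1
NCOR1
NCOR2
GPS2
CTBP1
CTBP2
RCOR1
RCOR2
RCOR3
GFI1
GFI1B
INSM1
ZEB1
ZEB2
SNAI1
SNAI2
KDM5D
CSR0001
CSR0002
CSR0003
CSR0004
CSR0005
CSR0006
CSR0007
CSR0008
CSR0009
CSR0010
CSR0011
CSR0012
CSR0013
CSR0014
CSR0015
CSR0016
CSR0017
CSR0018
CSR0019
CSR0020
CSR0021
CSR0022
CSR0023
CSR0024
CSR0025
CSR0026
CSR0027
CSR0028
CSR0029
CSR0030
CSR0031
CSR0032
CSR0033
CSR0034
CSR0035
CSR0036
CSR0037
CSR0038
CSR0039
CSR0040
CSR0041
CSR0042
CSR0043
CSR0044
CSR0045
CSR0046
CSR0047
CSR0048
CSR0049
CSR0050
CSR0051
CSR0052
CSR0053
CSR0054
CSR0055
CSR0056
CSR0057
CSR0058
CSR0059
CSR0060
CSR0061
CSR0062
CSR0063
CSR0064
CSR0065
CSR0066
CSR0067
CSR0068
CSR0069
CSR0070
CSR0071
CSR0072
CSR0073
CSR0074
CSR0075
CSR0076
CSR0077
CSR0078
CSR0079
CSR0080
CSR0081
CSR0082
CSR0083
CSR0084
CSR0085
CSR0086
CSR0087
CSR0088
CSR0089
CSR0090
CSR0091
CSR0092
CSR0093
CSR0094
CSR0095
CSR0096
CSR0097
CSR0098
CSR0099
CSR0100
CSR0101
CSR0102
CSR0103
CSR0104
CSR0105
CSR0106
CSR0107
CSR0108
CSR0109
CSR0110
CSR0111
CSR0112
CSR0113
CSR0114
CSR0115
CSR0116
CSR0117
CSR0118
CSR0119
CSR0120
CSR0121
CSR0122
CSR0123
CSR0124
CSR0125
CSR0126
CSR0127
CSR0128
CSR0129
CSR0130
CSR0131
CSR0132
CSR0133
CSR0134
CSR0135
CSR0136
CSR0137
CSR0138
CSR0139
CSR0140
CSR0141
CSR0142
CSR0143
CSR0144
CSR0145
CSR0146
CSR0147
CSR0148
CSR0149
CSR0150
CSR0151
CSR0152
CSR0153
CSR0154
CSR0155
CSR0156
CSR0157
CSR0158
CSR0159
CSR0160
CSR0161
CSR0162
CSR0163
CSR0164
CSR0165
CSR0166
CSR0167
CSR0168
CSR0169
CSR0170
CSR0171
CSR0172
CSR0173
CSR0174
CSR0175
CSR0176
CSR0177
CSR0178
CSR0179
CSR0180
CSR0181
CSR0182
CSR0183
CSR0184
CSR0185
CSR0186
CSR0187
CSR0188
CSR0189
CSR0190
CSR0191
CSR0192
CSR0193
CSR0194
CSR0195
CSR0196
CSR0197
CSR0198
CSR0199
CSR0200
CSR0201
CSR0202
CSR0203
CSR0204
CSR0205
CSR0206
CSR0207
CSR0208
CSR0209
CSR0210
CSR0211
CSR0212
CSR0213
CSR0214
CSR0215
CSR0216
CSR0217
CSR0218
CSR0219
CSR0220
CSR0221
CSR0222
CSR0223
CSR0224
CSR0225
CSR0226
CSR0227
CSR0228
CSR0229
CSR0230
CSR0231
CSR0232
CSR0233
CSR0234
CSR0235
CSR0236
CSR0237
CSR0238
CSR0239
CSR0240
CSR0241
CSR0242
CSR0243
CSR0244
CSR0245
CSR0246
CSR0247
CSR0248
CSR0249
CSR0250
CSR0251
CSR0252
CSR0253
CSR0254
CSR0255
CSR0256
CSR0257
CSR0258
CSR0259
CSR0260
CSR0261
CSR0262
CSR0263
CSR0264
CSR0265
CSR0266
CSR0267
CSR0268
CSR0269
CSR0270
CSR0271
CSR0272
CSR0273
CSR0274
CSR0275
CSR0276
CSR0277
CSR0278
CSR0279
CSR0280
CSR0281
CSR0282
CSR0283
CSR0284
CSR0285
CSR0286
CSR0287
CSR0288
CSR0289
CSR0290
CSR0291
CSR0292
CSR0293
CSR0294
CSR0295
CSR0296
CSR0297
CSR0298
CSR0299
CSR0300
CSR0301
CSR0302
CSR0303
CSR0304
CSR0305
CSR0306
CSR0307
CSR0308
CSR0309
CSR0310
CSR0311
CSR0312
CSR0313
CSR0314
CSR0315
CSR0316
CSR0317
CSR0318
CSR0319
CSR0320
CSR0321
CSR0322
CSR0323
CSR0324
CSR0325
CSR0326
CSR0327
CSR0328
CSR0329
CSR0330
CSR0331
CSR0332
CSR0333
CSR0334
CSR0335
CSR0336
CSR0337
CSR0338
CSR0339
CSR0340
CSR0341
CSR0342
CSR0343
CSR0344
CSR0345
CSR0346
CSR0347
CSR0348
CSR0349
CSR0350
CSR0351
CSR0352
CSR0353
CSR0354
CSR0355
CSR0356
CSR0357
CSR0358
CSR0359
CSR0360
CSR0361
CSR0362
CSR0363
CSR0364
CSR0365
CSR0366
CSR0367
CSR0368
CSR0369
CSR0370
CSR0371
CSR0372
CSR0373
CSR0374
CSR0375
CSR0376
CSR0377
CSR0378
CSR0379
CSR0380
CSR0381
CSR0382
CSR0383
CSR0384
CSR0385
CSR0386
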