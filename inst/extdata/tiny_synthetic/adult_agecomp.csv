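year,age,prop_escapement,prop_harvest
2003,4,0.1,0.07
2003,5,0.4,0.4
2003,6,0.46,0.5
2003,7,0.04,0.03
2004,4,0.03,0.06
2004,5,0.38,0.36
2004,6,0.57,0.56
2004,7,0.02,0.02
2005,4,0.05,0.02
2005,5,0.41,0.4
2005,6,0.48,0.57
2005,7,0.06,0.01
2006,4,0.04,0.05
2006,5,0.41,0.38
2006,6,0.51,0.55
2006,7,0.04,0.02
2007,4,0.02,0.02
2007,5,0.36,0.29
2007,6,0.54,0.65
2007,7,0.08,0.04
2008,4,0.07,0.02
2008,5,0.28,0.25
2008,6,0.6,0.7
2008,7,0.05,0.03
2009,4,0.05,0.03
2009,5,0.6,0.51
2009,6,0.31,0.41
2009,7,0.04,0.05
2010,4,0.27,0.16
2010,5,0.28,0.24
2010,6,0.43,0.58
2010,7,0.02,0.02
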