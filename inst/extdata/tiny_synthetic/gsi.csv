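year,age,n_genotyped,n_assigned_focal
2003,3,246,17
2003,4,379,25
2003,5,1391,60
2003,6,83,5
2004,3,273,15
2004,4,636,30
2004,5,2797,77
2004,6,177,8
2005,3,277,20
2005,4,672,28
2005,5,1455,81
2005,6,154,6
2006,3,245,3
2006,4,530,33
2006,5,1904,97
2006,6,192,10
2007,3,186,19
2007,4,290,18
2007,5,1693,75
2007,6,242,8
2008,3,103,7
2008,4,382,25
2008,5,1078,32
2008,6,139,8
2009,3,394,16
2009,4,158,7
2009,5,1035,54
2009,6,64,1
2010,3,253,4
2010,4,357,18
2010,5,294,23
2010,6,49,2
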