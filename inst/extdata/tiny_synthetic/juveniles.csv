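year,abundance
2003,1315253.44372447
2004,1739337.00558962
2006,951228.138149448
2007,795422.995132396
2009,2025035.61980801
2010,580959.149083201
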