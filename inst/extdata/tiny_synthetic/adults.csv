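year,escapement,harvest
2003,34190.0363176577,35956.6544262729
2004,35870.5206878357,36191.596663003
2005,36479.2127474747,25075.846228111
2006,37825.2540672879,26367.1440775042
2007,43405.7457706647,34546.1444200236
2008,29752.7412081271,24601.1633608649
2009,32465.9841965252,18177.3678104863
2010,37307.6366527122,16249.8378763776
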