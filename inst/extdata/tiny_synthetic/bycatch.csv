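year,total_count,n_scales
2003,21740.6716538792,2099
2004,43583.94017709,3883
2005,22228.8081602541,2558
2006,31667.7513693906,2871
2007,20261.6794529605,2411
2008,16773.1810174017,1702
2009,14480.1671174229,1651
2010,8936.2254155535,953
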