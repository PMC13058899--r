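{"size":"tiny","seed":1,"first_year":2003,"n_years":8,"log_alpha":3.87120101090789,"beta":1.2318608489985e-05,"sigma_R":0.5,"sB":[0.03,0.15,0.81,0.21],"v":[1,0.67,0.6,0.64,0.93],"sT":[0.5,0.8,1,0.9],"muG":[-2.94443897916644,-2.94443897916644,-2.94443897916644,-2.94443897916644],"sigmaG":[0.3,0.3,0.3,0.3],"genotyping_rate":0.1,"juvenile_missing_years":[2005,2008,2020]}
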