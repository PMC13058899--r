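year,age,prop
2003,3,0.102906145783707
2003,4,0.203906622201048
2003,5,0.646021915197713
2003,6,0.0471653168175322
2004,3,0.0628380118465104
2004,4,0.15606489827453
2004,5,0.74040690187999
2004,6,0.0406901879989699
2005,3,0.110242376856919
2005,4,0.257232212666145
2005,5,0.576231430805317
2005,6,0.0562939796716184
2006,3,0.0745384883315918
2006,4,0.189481017067224
2006,5,0.671891327063741
2006,6,0.0640891675374434
2007,3,0.0759021153048528
2007,4,0.111157196184156
2007,5,0.712152633761925
2007,6,0.100788054749067
2008,3,0.0769682726204465
2008,4,0.198002350176263
2008,5,0.643360752056404
2008,6,0.081668625146886
2009,3,0.236220472440945
2009,4,0.096305269533616
2009,5,0.632344033918837
2009,6,0.0351302241066021
2010,3,0.246589716684155
2010,4,0.375655823714586
2010,5,0.32109129066107
2010,6,0.0566631689401889
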