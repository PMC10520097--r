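region,era,rate
East Asia and Pacific,pre2000,0.25
East Asia and Pacific,2000-2010,0.15
East Asia and Pacific,post2010,0.10
Europe and Central Asia,pre2000,0.10
Europe and Central Asia,2000-2010,0.06
Europe and Central Asia,post2010,0.03
Latin America and Caribbean,pre2000,0.20
Latin America and Caribbean,2000-2010,0.12
Latin America and Caribbean,post2010,0.08
Middle East and North Africa,pre2000,0.35
Middle East and North Africa,2000-2010,0.25
Middle East and North Africa,post2010,0.15
North America,pre2000,0.00
North America,2000-2010,0.00
North America,post2010,0.00
South Asia,pre2000,0.45
South Asia,2000-2010,0.35
South Asia,post2010,0.25
Sub-Saharan Africa,pre2000,0.60
Sub-Saharan Africa,2000-2010,0.60
Sub-Saharan Africa,post2010,0.40
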