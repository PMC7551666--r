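maturity,age_years,median_weight_kg
preterm,0,1.2
preterm,0.0833,1.7
preterm,0.1667,2.1
preterm,0.25,2.5
term,0,3.4
term,0.0833,4.4
term,0.1667,5.3
term,0.25,6
term,0.5,7.5
term,0.75,8.6
term,1,9.5
term,1.5,11
term,2,12.2
term,2.5,13.2
term,3,14.3
term,4,16.3
term,5,18.3
term,6,20.5
term,7,23
term,8,25.7
term,9,28.6
term,10,32
term,11,36
term,12,40.5
term,13,45.5
term,14,50.5
term,15,55.5
term,16,60
term,17,64.5
term,18,70
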