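compound,tissue,mean,sd,available
erlotinib,brain,NA,NA,FALSE
erlotinib,lung,0.51,0.2,TRUE
erlotinib,spleen,1.46,0.4,TRUE
erlotinib,kidney,1.69,0.6,TRUE
erlotinib,bone,1.23,0.2,TRUE
erlotinib,tumor,1.42,0.5,TRUE
afatinib,brain,0.08,0.03,TRUE
afatinib,lung,2.54,1.2,TRUE
afatinib,spleen,13.23,2.3,TRUE
afatinib,kidney,6.93,1.8,TRUE
afatinib,bone,4.81,2,TRUE
afatinib,tumor,3.6,2.4,TRUE
osimertinib,brain,0.79,0.5,TRUE
osimertinib,lung,7.01,1.6,TRUE
osimertinib,spleen,18.09,7.7,TRUE
osimertinib,kidney,5.61,2,TRUE
osimertinib,bone,4.24,0.7,TRUE
osimertinib,tumor,5.6,2,TRUE
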