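city,variable,category,mean_early,mean_late,printed_pct_change
Boston,median_income,ungraded,82775,87525,5.7
Boston,median_income,A,94054,104553,11.2
Boston,median_income,D,52459,62484,19.1
Boston,median_home_value,D,296578,490727,65.5
Boston,total_population,B,4290,4448,3.7
Detroit,median_income,C,51629,38950,-24.6
Detroit,median_income,D,38652,29122,-24.7
Detroit,total_population,D,2886,2233,-22.6
Detroit,median_home_value,A,178241,119428,-33.0
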