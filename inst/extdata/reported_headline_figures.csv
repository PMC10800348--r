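quantity,period,value,unit
deforestation_rate,2004,27.8,thousand_km2
deforestation_rate,2007,11.7,thousand_km2
embargoes,2004-2011,19.6,thousand
embargoes,2012-2018,24.0,thousand
fines,2004-2011,52.0,thousand
fines,2012-2018,32.3,thousand
embargoed_area,2004-2011,1.4,Mha
embargoed_area,2012-2018,1.9,Mha
deforesting_holdings,2009-2018,53.3,thousand
illegal_deforesting_holdings,2009-2018,43.9,thousand
paid_fine_ratio_before,2004-2018,0.17,fraction
paid_fine_ratio_after,2019-2020,0.05,fraction
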