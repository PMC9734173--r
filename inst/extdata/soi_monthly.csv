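year,month,value,event
2010,Oct,18.3,Very strong La Nina
2010,Nov,16.4,Very strong La Nina
2010,Dec,27.1,Very strong La Nina
2010,Jan,19.9,Very strong La Nina
2011,Oct,7.3,Moderate La Nina
2011,Nov,13.8,Moderate La Nina
2011,Dec,23,Moderate La Nina
2011,Jan,9.4,Moderate La Nina
2012,Oct,2.4,Neutral
2012,Nov,3.9,Neutral
2012,Dec,-6,Neutral
2012,Jan,-1.1,Neutral
2013,Oct,-1.9,Neutral
2013,Nov,9.2,Neutral
2013,Dec,0.6,Neutral
2013,Jan,12.2,Neutral
2014,Oct,-8,El Nino alert
2014,Nov,-10,El Nino alert
2014,Dec,-5.5,El Nino alert
2014,Jan,-7.8,El Nino alert
2015,Oct,-20.2,Strong El Nino
2015,Nov,-5.3,Strong El Nino
2015,Dec,-9.1,Strong El Nino
2015,Jan,-19.7,Strong El Nino
2016,Oct,-4.3,Neutral-La Nina
2016,Nov,-0.7,Neutral-La Nina
2016,Dec,2.6,Neutral-La Nina
2016,Jan,1.3,Neutral-La Nina
2017,Oct,9.1,Neutral-La Nina
2017,Nov,11.8,Neutral-La Nina
2017,Dec,-1.4,Neutral-La Nina
2017,Jan,8.9,Neutral-La Nina
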