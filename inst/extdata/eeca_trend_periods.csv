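country,period,start_year,start_rate,pct_change,end_year,end_rate
Armenia,1,1990,562.0,19.6,1993,672.3
Armenia,2,1993,672.3,-32.1,2013,456.6
Armenia,3,2013,456.6,8.9,2019,497.1
Azerbaijan,1,1990,641.0,12.7,1994,722.3
Azerbaijan,2,1994,722.3,-32.0,2011,490.9
Azerbaijan,3,2011,490.9,13.5,2019,557.3
Belarus,1,1990,698.1,28.1,1995,894.5
Belarus,2,1995,894.5,-19.6,2011,719.1
Belarus,3,2011,719.1,-13.5,2019,622.3
Georgia,1,1990,788.7,2.8,1994,810.6
Georgia,2,1994,810.6,-20.6,2014,643.6
Georgia,3,2014,643.6,7.2,2019,690.2
Kazakhstan,1,1990,662.2,39.6,1996,924.6
Kazakhstan,2,1996,924.6,-11.0,2005,822.6
Kazakhstan,3,2005,822.6,-39.3,2019,499.2
Kyrgyzstan,1,1990,635.4,19.6,1994,759.9
Kyrgyzstan,2,1994,759.9,-26.2,2001,560.8
Kyrgyzstan,3,2001,560.8,-27.7,2019,405.4
Moldova,1,1990,633.9,23.9,1995,785.3
Moldova,2,1995,785.3,-17.8,1998,645.7
Moldova,3,1998,645.7,1.5,2010,655.5
Moldova,4,2010,655.5,-13.7,2019,565.4
Russia,1,1990,673.0,45.9,1994,981.7
Russia,2,1994,981.7,-8.9,2005,894.7
Russia,3,2005,894.7,-36.5,2019,567.8
Tajikistan,1,1990,561.0,8.6,1994,609.1
Tajikistan,2,1994,609.1,-29.8,2004,427.4
Tajikistan,3,2004,427.4,10.6,2019,472.7
Turkmenistan,1,1990,638.5,0.8,1992,643.3
Turkmenistan,2,1992,643.3,-9.8,2008,580.1
Turkmenistan,3,2008,580.1,-0.3,2019,578.1
Uzbekistan,1,1990,517.8,33.4,1996,690.5
Uzbekistan,2,1996,690.5,-16.8,2010,574.5
Uzbekistan,3,2010,574.5,6.3,2019,610.4
Ukraine,1,1990,743.1,28.8,1995,957.3
Ukraine,2,1995,957.3,-6.5,2005,895.0
Ukraine,3,2005,895.0,-32.0,2014,608.4
Ukraine,4,2014,608.4,29.5,2019,787.7
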