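gl,gna,gk,ga,gks,gca,gkca,gnap,gar,gampa,gnmda,ggaba,tau_ca,a_ampa,a_x_nmda,a_gaba,a_s_nmda,label,spike_rate,peak_hz
0.92890834687,43.93088339514,0.02778905236,0.50705049681,1.24971910029,0.08332302999,29.04224529900,0.54244701593,2.53676252404,0.413225529656,9.773894204805,0.060438569873,100.21833828,3.48,3.48,1,0.5,SWO,4.4,2.199560088
0.40642832854,61.42450860054,49.55060949847,17.11648052223,0.01761714812,0.07937762797,0.13672327824,5.49370094307,0.02965793469,0.146746503564,7.464440149234,1.548446555595,52.96364917,3.48,3.48,1,0.5,SWO,4.6,2.199560088
0.02991574419,0.02071731272,87.45713190141,1.45658439865,0.01270240213,54.96811090507,11.11618598054,1.02187576837,0.01552256260,0.602324304461,0.001260069416,0.003098946036,225.25629805,3.48,3.48,1,0.5,SWO_high,55.0,2.199560088
0.77588661918,26.44691178127,0.47204551398,0.01958749558,0.05317839354,0.13445315170,0.07231054895,0.07131630110,9.64661603362,0.077315800794,1.503333472015,0.019172406061,13.08292910,3.48,3.48,1,0.5,SWO,10.6,2.199560088
0.01045999595,0.02479891334,16.40393038267,37.37097943098,0.01803941042,2.69608407479,39.26284791713,0.42297377331,0.03438966505,0.009857086232,2.771707989654,0.038985770491,630.15499660,3.48,3.48,1,0.5,SWO,8.0,2.399520096
0.02096081706,6.61714275685,5.86606037479,0.45082013083,1.02802178105,0.48394222512,1.30178670515,0.50810529416,0.06948826507,0.002138231080,3.415410350836,0.670779833389,579.63856017,3.48,3.48,1,0.5,SWO,5.6,2.799440112
0.90172939056,19.81564064072,38.22488880571,0.05781793092,0.01312346631,1.95819848336,0.38753613950,0.02317637127,0.09409649612,0.038957843046,5.846815872828,0.015944978337,63.89948461,3.48,3.48,1,0.5,SWO,9.6,3.199360128
0.50287492149,0.01790865949,0.02670423140,1.61019653751,1.40380845613,58.06287205425,16.02588580894,0.16197371853,0.23592198683,0.001751896741,0.002629371641,0.001646598328,75.30949674,3.48,3.48,1,0.5,SWO_high,128.5,3.199360128
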