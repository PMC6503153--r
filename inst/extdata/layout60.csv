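label,x,y,z
E01,9.1997,0,0.0767
E02,-6.7817,6.2126,0.23
E03,0.8036,-9.1568,0.3833
E04,5.5881,7.2887,0.5367
E05,-9.0338,-1.598,0.69
E06,7.7299,-4.9171,0.8433
E07,-2.3743,8.8323,0.9967
E08,-4.2071,-8.1005,1.15
E09,8.5546,3.1241,1.3033
E10,-8.3967,3.466,1.4567
E11,3.8392,-8.2042,1.61
E12,2.7024,8.6156,1.7633
E13,-7.7853,-4.5117,1.9167
E14,8.755,-1.9248,2.07
E15,-5.1344,7.3031,2.2233
E16,-1.1422,-8.814,2.3767
E17,6.7635,5.7003,2.53
E18,-8.7925,0.3636,2.6833
E19,6.2035,-6.1733,2.8367
E20,-0.4019,8.6913,2.99
E21,-5.5398,-6.6385,3.1433
E22,8.5124,1.1453,3.2967
E23,-7.0008,4.871,3.45
E24,1.8579,-8.2586,3.6033
E25,4.1754,7.2866,3.7567
E26,-7.9338,-2.5311,3.91
E27,7.493,-3.4619,4.0633
E28,-3.1567,7.5429,4.2167
E29,-2.7401,-7.6181,4.37
E30,7.0914,3.7271,4.5233
E31,-7.661,2.0194,4.6767
E32,4.2348,-6.5861,4.83
E33,1.3099,7.6217,4.9833
E34,-6.0344,-4.6734,5.1367
E35,7.5013,-0.6215,5.29
E36,-5.0367,5.4445,5.4433
E37,0.0356,-7.3018,5.5967
E38,4.8253,5.3192,5.75
E39,-7.0261,-0.6512,5.9033
E40,5.5162,-4.1866,6.0567
E41,-1.2149,6.6783,6.21
E42,-3.5388,-5.6236,6.3633
E43,6.2631,1.7165,6.5167
E44,-5.6375,2.8931,6.67
E45,2.1452,-5.7862,6.8233
E46,2.2612,5.5546,6.9767
E47,-5.2539,-2.4899,7.13
E48,5.3713,-1.656,7.2833
E49,-2.7386,4.6729,7.4367
E50,-1.0916,-5.0833,7.59
E51,4.0501,2.877,7.7433
E52,-4.6842,0.5838,7.8967
E53,2.8869,-3.3917,8.05
E54,0.1518,4.162,8.2033
E55,-2.7009,-2.7407,8.3567
E56,3.4911,0.1785,8.51
E57,-2.3869,1.9722,8.6633
E58,0.3631,-2.6028,8.8167
E59,1.1594,1.6837,8.97
E60,-1.1551,-0.2658,9.1233
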