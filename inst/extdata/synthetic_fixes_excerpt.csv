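"animal_id","timestamp","x","y"
"B2","2014-05-10 00:00:00",509201.175,6834844.117
"B2","2014-05-10 01:00:00",509121.287,6834941.52
"B2","2014-05-10 02:00:00",509055.571,6835046.318
"B2","2014-05-10 03:00:00",508984.272,6835138.784
"B2","2014-05-10 04:00:00",508906.328,6835230.303
"B2","2014-05-10 05:00:00",508845.84,6835333.507
"B2","2014-05-10 06:00:00",508771.278,6835430.064
"B2","2014-05-10 07:00:00",508699.976,6835533.588
"B2","2014-05-10 08:00:00",508630.555,6835624.706
"B2","2014-05-10 09:00:00",508554.29,6835725.661
"B2","2014-05-10 10:00:00",508480.519,6835824.306
"B2","2014-05-10 11:00:00",508409.67,6835919.6
"B2","2014-05-10 12:00:00",508340.683,6836018.535
"B2","2014-05-10 13:00:00",508267.329,6836113.255
"B2","2014-05-10 14:00:00",508194.607,6836207.719
"B2","2014-05-10 15:00:00",508129.274,6836307.416
"B2","2014-05-10 16:00:00",508060.068,6836409.44
"B2","2014-05-10 17:00:00",507985.027,6836510.621
"B2","2014-05-10 18:00:00",507928.886,6836595.713
"B2","2014-05-10 19:00:00",507846.11,6836704.685
"B2","2014-05-10 20:00:00",507773.537,6836800.337
"B2","2014-05-10 21:00:00",507696.596,6836897.334
"B2","2014-05-10 22:00:00",507629.514,6837001.057
"B2","2014-05-10 23:00:00",507555.086,6837095.129
"B2","2014-05-11 00:00:00",507481.838,6837192.722
"B2","2014-05-11 01:00:00",507424.023,6837275.519
"B2","2014-05-11 02:00:00",507339.998,6837381.177
"B2","2014-05-11 03:00:00",507284.113,6837479.975
"B2","2014-05-11 04:00:00",507209.321,6837579.757
"B2","2014-05-11 05:00:00",507142.169,6837675.436
"B2","2014-05-11 06:00:00",507066.718,6837772.681
"B2","2014-05-11 07:00:00",506988.666,6837872.579
"B2","2014-05-11 08:00:00",506925.57,6837969.152
"B2","2014-05-11 09:00:00",506847.045,6838066.431
"B2","2014-05-11 10:00:00",506776.89,6838155.569
"B2","2014-05-11 11:00:00",506706.279,6838255.758
"B2","2014-05-11 12:00:00",506639.175,6838367.346
"B2","2014-05-11 13:00:00",506558.004,6838458.62
"B2","2014-05-11 14:00:00",506490.924,6838559.785
"B2","2014-05-11 15:00:00",506429.56,6838652.698
"B2","2014-05-11 16:00:00",506353.111,6838750.578
"B2","2014-05-11 17:00:00",506280.472,6838844.967
"B2","2014-05-11 18:00:00",506211.763,6838941.109
"B2","2014-05-11 19:00:00",506136.681,6839047.225
"B2","2014-05-11 20:00:00",506068.558,6839133.458
"B2","2014-05-11 21:00:00",505988.749,6839240.354
"B2","2014-05-11 22:00:00",505917.765,6839338.582
"B2","2014-05-11 23:00:00",505850.018,6839433.174
"B2","2014-05-12 00:00:00",505778.527,6839536.204
"B2","2014-05-12 01:00:00",505712.971,6839627.293
"B2","2014-05-12 02:00:00",505641.327,6839728.99
"B2","2014-05-12 03:00:00",505564.688,6839818.652
"B2","2014-05-12 04:00:00",505496.879,6839924.947
"B2","2014-05-12 05:00:00",505430.888,6840014.694
"B2","2014-05-12 06:00:00",505365.649,6840115.22
"B2","2014-05-12 07:00:00",505287.342,6840222.958
"B2","2014-05-12 08:00:00",505206.02,6840304.528
"B2","2014-05-12 09:00:00",505147.295,6840407.979
"B2","2014-05-12 09:10:00",505133.829,6840424.275
"B2","2014-05-12 09:20:00",505120.364,6840440.571
"B2","2014-05-12 09:30:00",505106.899,6840456.867
"B2","2014-05-12 09:40:00",505093.434,6840473.163
"B2","2014-05-12 09:50:00",505079.969,6840489.459
"B2","2014-05-12 10:00:00",505066.503,6840505.755
"B2","2014-05-12 10:10:00",505055.567,6840522.267
"B2","2014-05-12 10:20:00",505044.632,6840538.78
"B2","2014-05-12 10:30:00",505033.696,6840555.293
"B2","2014-05-12 10:40:00",505022.76,6840571.806
"B2","2014-05-12 10:50:00",505011.824,6840588.318
"B2","2014-05-12 11:00:00",505000.888,6840604.831
"B2","2014-05-12 11:10:00",504987.509,6840620.846
"B2","2014-05-12 11:20:00",504974.131,6840636.86
"B2","2014-05-12 11:30:00",504960.752,6840652.875
"B2","2014-05-12 11:40:00",504947.373,6840668.889
"B2","2014-05-12 11:50:00",504933.995,6840684.904
"B2","2014-05-12 12:00:00",504920.616,6840700.918
"B2","2014-05-12 12:10:00",504911.36,6840717.039
"B2","2014-05-12 12:20:00",504902.105,6840733.161
"B2","2014-05-12 12:30:00",504892.85,6840749.282
"B2","2014-05-12 12:40:00",504883.594,6840765.403
"B2","2014-05-12 12:50:00",504874.339,6840781.524
"B2","2014-05-12 13:00:00",504865.083,6840797.645
"B2","2014-05-12 13:10:00",504852.754,6840813.041
"B2","2014-05-12 13:20:00",504840.426,6840828.437
"B2","2014-05-12 13:30:00",504828.097,6840843.833
"B2","2014-05-12 13:40:00",504815.768,6840859.228
"B2","2014-05-12 13:50:00",504803.439,6840874.624
"B2","2014-05-12 14:00:00",504791.11,6840890.02
"B2","2014-05-12 14:10:00",504778.708,6840909.197
"B2","2014-05-12 14:20:00",504766.306,6840928.374
"B2","2014-05-12 14:30:00",504753.904,6840947.552
"B2","2014-05-12 14:40:00",504741.502,6840966.729
"B2","2014-05-12 14:50:00",504729.101,6840985.906
"B2","2014-05-12 15:00:00",504716.699,6841005.083
"B2","2014-05-12 16:00:00",504649.427,6841090.844
"B2","2014-05-12 17:00:00",504573.335,6841190.497
"B2","2014-05-12 18:00:00",504508.61,6841288.841
"B2","2014-05-12 19:00:00",504436.484,6841388.422
"B2","2014-05-12 20:00:00",504357.34,6841486.85
"B2","2014-05-12 21:00:00",504289.639,6841577.406
"B2","2014-05-12 22:00:00",504224.211,6841680.564
"B2","2014-05-12 23:00:00",504147.966,6841775.408
"B2","2014-05-13 00:00:00",504072.81,6841880.598
"B2","2014-05-13 01:00:00",504009.572,6841978.646
"B2","2014-05-13 02:00:00",503947.457,6842067.268
"B2","2014-05-13 03:00:00",503866.876,6842170.146
"B2","2014-05-13 04:00:00",503793.906,6842264.908
"B2","2014-05-13 05:00:00",503718.409,6842370.238
"B2","2014-05-13 06:00:00",503647.093,6842470.062
"B2","2014-05-13 07:00:00",503581.134,6842563.505
"B2","2014-05-13 08:00:00",503508.127,6842647.728
"B2","2014-05-13 09:00:00",503427.662,6842757.072
"B2","2014-05-13 10:00:00",503360.378,6842861.129
"B2","2014-05-13 11:00:00",503293.483,6842948.471
"B2","2014-05-13 12:00:00",503227.013,6843053.215
"B2","2014-05-13 13:00:00",503153.662,6843145.278
"B2","2014-05-13 14:00:00",503087.451,6843241.136
"B2","2014-05-13 15:00:00",503012.17,6843337.922
"B2","2014-05-13 16:00:00",502946.024,6843439.166
"B2","2014-05-13 17:00:00",502866.961,6843543.299
"B2","2014-05-13 18:00:00",502799.656,6843636.654
"B2","2014-05-13 19:00:00",502726.885,6843720.904
"B2","2014-05-13 20:00:00",502661.763,6843828.438
"B2","2014-05-13 21:00:00",502584.133,6843925.608
"B2","2014-05-13 22:00:00",502506.935,6844024.634
"B2","2014-05-13 23:00:00",502443.097,6844121.027
"B2","2014-05-14 00:00:00",502370.859,6844216.962
"B2","2014-05-14 01:00:00",502299.879,6844314.397
"B2","2014-05-14 02:00:00",502235.339,6844414.812
"B2","2014-05-14 03:00:00",502167.659,6844510.817
"B2","2014-05-14 04:00:00",502082.893,6844607.328
"B2","2014-05-14 05:00:00",502017.522,6844713.227
"B2","2014-05-14 06:00:00",501942.702,6844801.732
"B2","2014-05-14 07:00:00",501871.983,6844904.771
"B2","2014-05-14 08:00:00",501797.808,6845004.69
"B2","2014-05-14 09:00:00",501731.38,6845098.828
"B2","2014-05-14 10:00:00",501656.247,6845200.781
"B2","2014-05-14 11:00:00",501588.713,6845297.968
"B2","2014-05-14 12:00:00",501520.837,6845398.01
"B2","2014-05-14 13:00:00",501451.401,6845492.35
"B2","2014-05-14 14:00:00",501372.359,6845588.709
"B2","2014-05-14 15:00:00",501309.856,6845692.901
"B2","2014-05-14 16:00:00",501231.992,6845774.493
"B2","2014-05-14 17:00:00",501164.227,6845879.193
"B2","2014-05-14 18:00:00",501086.018,6845976.722
"B2","2014-05-14 19:00:00",501018.845,6846075.895
"B2","2014-05-14 20:00:00",500954.013,6846172.058
"B2","2014-05-14 21:00:00",500877.273,6846266.221
"B2","2014-05-14 22:00:00",500807.1,6846375.341
"B2","2014-05-14 23:00:00",500728.871,6846463.812
"B2","2014-05-15 00:00:00",500662.043,6846558.917
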