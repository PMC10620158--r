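wound_id,animal,treatment,frame,time_s,area_mm2
control_w1,control_a1,control,0,0,0.0453305
control_w1,control_a1,control,10,110,0.0395603
control_w1,control_a1,control,20,220,0.0362432
control_w1,control_a1,control,30,330,0.0296782
control_w1,control_a1,control,40,440,0.0280246
control_w1,control_a1,control,50,550,0.029964
control_w1,control_a1,control,60,660,0.026277
control_w1,control_a1,control,70,770,0.0216958
control_w1,control_a1,control,80,880,0.0205253
control_w1,control_a1,control,90,990,0.0158978
control_w1,control_a1,control,100,1100,0.014336
control_w1,control_a1,control,110,1210,0.0140028
control_w1,control_a1,control,120,1320,0.0115771
control_w1,control_a1,control,130,1430,0.0112735
control_w1,control_a1,control,140,1540,0.0103688
control_w1,control_a1,control,150,1650,0.00781877
control_w1,control_a1,control,160,1760,0.00846861
control_w1,control_a1,control,170,1870,0.00665241
control_w1,control_a1,control,180,1980,0.00667348
control_w2,control_a2,control,0,0,0.0423513
control_w2,control_a2,control,10,110,0.0434187
control_w2,control_a2,control,20,220,0.047008
control_w2,control_a2,control,30,330,0.033155
control_w2,control_a2,control,40,440,0.0314674
control_w2,control_a2,control,50,550,0.0316573
control_w2,control_a2,control,60,660,0.0258403
control_w2,control_a2,control,70,770,0.0216688
control_w2,control_a2,control,80,880,0.0245466
control_w2,control_a2,control,90,990,0.0184553
control_w2,control_a2,control,100,1100,0.0162921
control_w2,control_a2,control,110,1210,0.0171854
control_w2,control_a2,control,120,1320,0.014062
control_w2,control_a2,control,130,1430,0.0112853
control_w2,control_a2,control,140,1540,0.0116539
control_w2,control_a2,control,150,1650,0.00895657
control_w2,control_a2,control,160,1760,0.0083086
control_w2,control_a2,control,170,1870,0.00810421
control_w2,control_a2,control,180,1980,0.00679767
control_w3,control_a3,control,0,0,0.0599478
control_w3,control_a3,control,10,110,0.0467288
control_w3,control_a3,control,20,220,0.0468154
control_w3,control_a3,control,30,330,0.0444203
control_w3,control_a3,control,40,440,0.0370241
control_w3,control_a3,control,50,550,0.0300248
control_w3,control_a3,control,60,660,0.0327051
control_w3,control_a3,control,70,770,0.0240052
control_w3,control_a3,control,80,880,0.020365
control_w3,control_a3,control,90,990,0.0203888
control_w3,control_a3,control,100,1100,0.0187925
control_w3,control_a3,control,110,1210,0.0137666
control_w3,control_a3,control,120,1320,0.0138842
control_w3,control_a3,control,130,1430,0.0135149
control_w3,control_a3,control,140,1540,0.0130647
control_w3,control_a3,control,150,1650,0.0102706
control_w3,control_a3,control,160,1760,0.0100291
control_w3,control_a3,control,170,1870,0.00866394
control_w3,control_a3,control,180,1980,0.00803912
control_w4,control_a4,control,0,0,0.0637195
control_w4,control_a4,control,10,110,0.0539579
control_w4,control_a4,control,20,220,0.0461008
control_w4,control_a4,control,30,330,0.0388643
control_w4,control_a4,control,40,440,0.0392199
control_w4,control_a4,control,50,550,0.0324765
control_w4,control_a4,control,60,660,0.0317872
control_w4,control_a4,control,70,770,0.0257742
control_w4,control_a4,control,80,880,0.0212457
control_w4,control_a4,control,90,990,0.0203887
control_w4,control_a4,control,100,1100,0.0214142
control_w4,control_a4,control,110,1210,0.0171399
control_w4,control_a4,control,120,1320,0.0144185
control_w4,control_a4,control,130,1430,0.0140652
control_w4,control_a4,control,140,1540,0.0126599
control_w4,control_a4,control,150,1650,0.0125335
control_w4,control_a4,control,160,1760,0.0101889
control_w4,control_a4,control,170,1870,0.0100133
control_w4,control_a4,control,180,1980,0.00811011
treated_w1,treated_a1,treated,0,0,0.0480673
treated_w1,treated_a1,treated,10,110,0.0413111
treated_w1,treated_a1,treated,20,220,0.0403913
treated_w1,treated_a1,treated,30,330,0.0404072
treated_w1,treated_a1,treated,40,440,0.0347017
treated_w1,treated_a1,treated,50,550,0.0298783
treated_w1,treated_a1,treated,60,660,0.0309638
treated_w1,treated_a1,treated,70,770,0.0345765
treated_w1,treated_a1,treated,80,880,0.0268928
treated_w1,treated_a1,treated,90,990,0.0241416
treated_w1,treated_a1,treated,100,1100,0.0263141
treated_w1,treated_a1,treated,110,1210,0.0238895
treated_w1,treated_a1,treated,120,1320,0.0208958
treated_w1,treated_a1,treated,130,1430,0.0247594
treated_w1,treated_a1,treated,140,1540,0.0227134
treated_w1,treated_a1,treated,150,1650,0.0222714
treated_w1,treated_a1,treated,160,1760,0.0181136
treated_w1,treated_a1,treated,170,1870,0.0180924
treated_w1,treated_a1,treated,180,1980,0.0151546
treated_w2,treated_a2,treated,0,0,0.0485115
treated_w2,treated_a2,treated,10,110,0.0486774
treated_w2,treated_a2,treated,20,220,0.0427531
treated_w2,treated_a2,treated,30,330,0.0430042
treated_w2,treated_a2,treated,40,440,0.038576
treated_w2,treated_a2,treated,50,550,0.0386503
treated_w2,treated_a2,treated,60,660,0.0339631
treated_w2,treated_a2,treated,70,770,0.0295381
treated_w2,treated_a2,treated,80,880,0.0341259
treated_w2,treated_a2,treated,90,990,0.0286575
treated_w2,treated_a2,treated,100,1100,0.0247776
treated_w2,treated_a2,treated,110,1210,0.0282179
treated_w2,treated_a2,treated,120,1320,0.0269124
treated_w2,treated_a2,treated,130,1430,0.0260208
treated_w2,treated_a2,treated,140,1540,0.0201191
treated_w2,treated_a2,treated,150,1650,0.0227674
treated_w2,treated_a2,treated,160,1760,0.0190085
treated_w2,treated_a2,treated,170,1870,0.020588
treated_w2,treated_a2,treated,180,1980,0.0197994
treated_w3,treated_a3,treated,0,0,0.0587316
treated_w3,treated_a3,treated,10,110,0.0572293
treated_w3,treated_a3,treated,20,220,0.0534924
treated_w3,treated_a3,treated,30,330,0.0468357
treated_w3,treated_a3,treated,40,440,0.0441704
treated_w3,treated_a3,treated,50,550,0.04058
treated_w3,treated_a3,treated,60,660,0.0422556
treated_w3,treated_a3,treated,70,770,0.0391628
treated_w3,treated_a3,treated,80,880,0.0305477
treated_w3,treated_a3,treated,90,990,0.0338784
treated_w3,treated_a3,treated,100,1100,0.0345367
treated_w3,treated_a3,treated,110,1210,0.02866
treated_w3,treated_a3,treated,120,1320,0.0277345
treated_w3,treated_a3,treated,130,1430,0.0265079
treated_w3,treated_a3,treated,140,1540,0.0249605
treated_w3,treated_a3,treated,150,1650,0.023692
treated_w3,treated_a3,treated,160,1760,0.025318
treated_w3,treated_a3,treated,170,1870,0.0220621
treated_w3,treated_a3,treated,180,1980,0.0208619
treated_w4,treated_a4,treated,0,0,0.055926
treated_w4,treated_a4,treated,10,110,0.0522304
treated_w4,treated_a4,treated,20,220,0.0521871
treated_w4,treated_a4,treated,30,330,0.0494416
treated_w4,treated_a4,treated,40,440,0.0469588
treated_w4,treated_a4,treated,50,550,0.0391227
treated_w4,treated_a4,treated,60,660,0.0436403
treated_w4,treated_a4,treated,70,770,0.0416468
treated_w4,treated_a4,treated,80,880,0.0388637
treated_w4,treated_a4,treated,90,990,0.0361196
treated_w4,treated_a4,treated,100,1100,0.0314986
treated_w4,treated_a4,treated,110,1210,0.0326496
treated_w4,treated_a4,treated,120,1320,0.0322001
treated_w4,treated_a4,treated,130,1430,0.0252934
treated_w4,treated_a4,treated,140,1540,0.0326266
treated_w4,treated_a4,treated,150,1650,0.0279113
treated_w4,treated_a4,treated,160,1760,0.027987
treated_w4,treated_a4,treated,170,1870,0.0210794
treated_w4,treated_a4,treated,180,1980,0.0208571
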