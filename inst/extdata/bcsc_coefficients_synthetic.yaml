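description: 'Synthetic stand-in coefficient set with the structure of a BCSC-style
  5-year risk model: multiplicative relative risks over density, binary first-degree
  family history and biopsy pathology, plus per-stratum annual baseline and competing
  hazards by single year of age. Values are invented but epidemiologically plausible
  placeholders; the published tables can be supplied in the same format.'
rr_table:
  age_bands:
  - ages:
    - 40
    - 80
    density:
      a: 0.6
      b: 1.0
      c: 1.5
      d: 2.1
      unknown: 1.0
    fdr:
      'no': 1.0
      'yes': 1.6
    biopsy:
      none: 1.0
      nonproliferative: 1.1
      proliferative_no_atypia: 1.4
      atypia: 1.9
      lcis: 2.5
      unknown: 1.0
hazards:
  nh_white:
    age_start: 40
    baseline:
    - 0.0012
    - 0.0012552
    - 0.001313
    - 0.0013734
    - 0.0014367
    - 0.0015028
    - 0.001572
    - 0.0016443
    - 0.00172
    - 0.0017992
    - 0.001882
    - 0.0019686
    - 0.0020592
    - 0.002154
    - 0.0022531
    - 0.0023568
    - 0.0024653
    - 0.0025788
    - 0.0026975
    - 0.0028216
    - 0.0029515
    - 0.0030874
    - 0.0032295
    - 0.0033781
    - 0.0035336
    - 0.0036963
    - 0.0038664
    - 0.0040444
    - 0.0042305
    - 0.0044252
    - 0.0046289
    - 0.004842
    - 0.0050648
    - 0.005298
    - 0.0055418
    - 0.0057969
    - 0.0060637
    - 0.0063428
    - 0.0066348
    - 0.0069401
    - 0.0072596
    competing:
    - 0.002
    - 0.002145
    - 0.0023005
    - 0.0024674
    - 0.0026463
    - 0.0028381
    - 0.0030439
    - 0.0032646
    - 0.0035013
    - 0.0037552
    - 0.0040275
    - 0.0043195
    - 0.0046327
    - 0.0049686
    - 0.0053289
    - 0.0057153
    - 0.0061297
    - 0.0065742
    - 0.0070508
    - 0.0075621
    - 0.0081104
    - 0.0086985
    - 0.0093292
    - 0.010006
    - 0.010731
    - 0.011509
    - 0.012344
    - 0.013239
    - 0.014199
    - 0.015228
    - 0.016332
    - 0.017517
    - 0.018787
    - 0.020149
    - 0.02161
    - 0.023177
    - 0.024857
    - 0.02666
    - 0.028593
    - 0.030666
    - 0.032889
  nh_black:
    age_start: 40
    baseline:
    - 0.00114
    - 0.0011925
    - 0.0012474
    - 0.0013048
    - 0.0013648
    - 0.0014276
    - 0.0014934
    - 0.0015621
    - 0.001634
    - 0.0017092
    - 0.0017879
    - 0.0018702
    - 0.0019562
    - 0.0020463
    - 0.0021405
    - 0.002239
    - 0.0023421
    - 0.0024499
    - 0.0025626
    - 0.0026806
    - 0.0028039
    - 0.002933
    - 0.003068
    - 0.0032092
    - 0.0033569
    - 0.0035114
    - 0.0036731
    - 0.0038421
    - 0.004019
    - 0.004204
    - 0.0043975
    - 0.0045999
    - 0.0048116
    - 0.0050331
    - 0.0052647
    - 0.005507
    - 0.0057605
    - 0.0060257
    - 0.006303
    - 0.0065931
    - 0.0068966
    competing:
    - 0.0026
    - 0.0027885
    - 0.0029907
    - 0.0032076
    - 0.0034401
    - 0.0036896
    - 0.0039571
    - 0.004244
    - 0.0045517
    - 0.0048818
    - 0.0052358
    - 0.0056154
    - 0.0060226
    - 0.0064592
    - 0.0069276
    - 0.0074299
    - 0.0079686
    - 0.0085464
    - 0.0091661
    - 0.0098307
    - 0.010544
    - 0.011308
    - 0.012128
    - 0.013007
    - 0.01395
    - 0.014962
    - 0.016047
    - 0.01721
    - 0.018458
    - 0.019797
    - 0.021232
    - 0.022772
    - 0.024423
    - 0.026194
    - 0.028093
    - 0.03013
    - 0.032314
    - 0.034657
    - 0.03717
    - 0.039866
    - 0.042756
  hispanic:
    age_start: 40
    baseline:
    - 0.00096
    - 0.0010042
    - 0.0010504
    - 0.0010988
    - 0.0011493
    - 0.0012022
    - 0.0012576
    - 0.0013154
    - 0.001376
    - 0.0014393
    - 0.0015056
    - 0.0015749
    - 0.0016474
    - 0.0017232
    - 0.0018025
    - 0.0018855
    - 0.0019723
    - 0.002063
    - 0.002158
    - 0.0022573
    - 0.0023612
    - 0.0024699
    - 0.0025836
    - 0.0027025
    - 0.0028269
    - 0.002957
    - 0.0030931
    - 0.0032355
    - 0.0033844
    - 0.0035402
    - 0.0037031
    - 0.0038736
    - 0.0040519
    - 0.0042384
    - 0.0044334
    - 0.0046375
    - 0.004851
    - 0.0050742
    - 0.0053078
    - 0.0055521
    - 0.0058077
    competing:
    - 0.0018
    - 0.0019305
    - 0.0020705
    - 0.0022206
    - 0.0023816
    - 0.0025543
    - 0.0027395
    - 0.0029382
    - 0.0031512
    - 0.0033797
    - 0.0036248
    - 0.0038876
    - 0.0041695
    - 0.0044718
    - 0.004796
    - 0.0051438
    - 0.0055167
    - 0.0059167
    - 0.0063458
    - 0.0068059
    - 0.0072994
    - 0.0078286
    - 0.0083963
    - 0.0090051
    - 0.009658
    - 0.010358
    - 0.011109
    - 0.011915
    - 0.012779
    - 0.013705
    - 0.014699
    - 0.015765
    - 0.016908
    - 0.018134
    - 0.019449
    - 0.020859
    - 0.022371
    - 0.023994
    - 0.025733
    - 0.027599
    - 0.0296
  nh_asian:
    age_start: 40
    baseline:
    - 0.0009
    - 0.0009414
    - 0.0009848
    - 0.0010301
    - 0.0010775
    - 0.0011271
    - 0.001179
    - 0.0012332
    - 0.00129
    - 0.0013494
    - 0.0014115
    - 0.0014764
    - 0.0015444
    - 0.0016155
    - 0.0016898
    - 0.0017676
    - 0.001849
    - 0.0019341
    - 0.0020231
    - 0.0021162
    - 0.0022136
    - 0.0023155
    - 0.0024221
    - 0.0025336
    - 0.0026502
    - 0.0027722
    - 0.0028998
    - 0.0030333
    - 0.0031729
    - 0.0033189
    - 0.0034717
    - 0.0036315
    - 0.0037986
    - 0.0039735
    - 0.0041564
    - 0.0043477
    - 0.0045478
    - 0.0047571
    - 0.0049761
    - 0.0052051
    - 0.0054447
    competing:
    - 0.0016
    - 0.001716
    - 0.0018404
    - 0.0019739
    - 0.002117
    - 0.0022705
    - 0.0024351
    - 0.0026117
    - 0.0028011
    - 0.0030042
    - 0.003222
    - 0.0034556
    - 0.0037062
    - 0.0039749
    - 0.0042631
    - 0.0045722
    - 0.0049038
    - 0.0052593
    - 0.0056407
    - 0.0060497
    - 0.0064883
    - 0.0069588
    - 0.0074633
    - 0.0080045
    - 0.0085849
    - 0.0092074
    - 0.009875
    - 0.010591
    - 0.011359
    - 0.012183
    - 0.013066
    - 0.014013
    - 0.015029
    - 0.016119
    - 0.017288
    - 0.018541
    - 0.019886
    - 0.021328
    - 0.022874
    - 0.024533
    - 0.026311
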