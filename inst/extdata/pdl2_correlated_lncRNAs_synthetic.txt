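LINC00877
LINC01094
LINC01272
LINC10128
LINC11727
LINC11821
LINC14747
LINC14972
LINC15093
LINC15207
LINC17602
LINC17959
LINC19398
LINC20986
LINC23413
LINC24496
LINC24769
LINC24812
LINC26795
LINC28216
LINC29356
LINC30605
LINC31571
LINC31617
LINC35279
LINC36357
LINC38938
LINC40198
LINC40456
LINC41928
LINC42431
LINC43430
LINC43545
LINC44260
LINC44577
LINC44863
LINC44963
LINC47346
LINC47990
LINC48108
LINC48440
LINC48895
LINC50354
LINC54176
LINC54396
LINC55851
LINC56151
LINC58182
LINC58611
LINC59373
LINC59621
LINC62369
LINC62457
LINC63083
LINC63299
LINC66414
LINC67600
LINC67615
LINC70268
LINC71695
LINC72357
LINC73275
LINC74080
LINC77806
LINC80156
LINC80976
LINC81334
LINC82393
LINC83735
LINC84705
LINC86951
LINC87152
LINC88137
LINC88502
LINC88591
LINC89490
LINC90823
LINC91350
LINC94543
LINC95117
LINC95705
LINC97258
LINC98011
PIK3CD-AS1
SIRPG-AS1
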