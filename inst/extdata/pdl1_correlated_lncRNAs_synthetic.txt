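LINC00877
LINC01094
LINC01272
LINC23413
LINC24496
LINC30605
LINC32286
LINC40169
LINC40198
LINC43430
LINC44260
LINC44577
LINC47990
LINC50354
LINC53957
LINC58611
LINC62457
LINC63610
LINC67600
LINC71695
LINC74080
LINC83406
LINC87152
LINC90810
LINC91350
LINC95117
LINC95608
PIK3CD-AS1
SIRPG-AS1
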