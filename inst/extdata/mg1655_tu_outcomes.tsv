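tu_id	essential_observed	complementation_note	impairment_note
alaWX	0		very_impaired
argQZYV-serV	1	natural promoter
argU	1	lpp promoter required
argW	0
argX-hisR-leuT-proM	1	natural promoter
asnT	0
asnU	0
asnV	0
asnW	0
aspV	0
glyU	0
glyVXY	0
glyW-cysT-leuZ	1	natural promoter
ileX	1	natural promoter
ileY	0
leuU	0
leuVPQ	0
leuX	0
lysT-valT-lysW-valZ-lysYZQ	1	natural promoter
metT-leuW-glnUW-metU-glnVX	1	natural promoter
metY	0
metZWV	0		very_impaired
pheU	0
pheV	0
proK	0
proL	0
rrnA	0
rrnB	0
rrnC	1	lpp promoter required
rrnD	0
rrnE	0
rrnG	0
rrnH	0
selC	0
serT	1	natural promoter
serU	0
serW	0
serX	0
thrU-tyrU-glyT-thrT	1	natural promoter
thrW	0
tyrTV	0
valUXY-lysV	0
valVW	0		very_impaired
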