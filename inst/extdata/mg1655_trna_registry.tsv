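gene	amino_acid	anticodon	modification	class	tu_id	tu_display_name	tu_non_trna
alaW	Ala	GGC		elongator	alaWX	alaWX	0
alaX	Ala	GGC		elongator	alaWX	alaWX	0
argQ	Arg	ACG	I	elongator	argQZYV-serV	argQZYV-serV	0
argZ	Arg	ACG	I	elongator	argQZYV-serV	argQZYV-serV	0
argY	Arg	ACG	I	elongator	argQZYV-serV	argQZYV-serV	0
argV	Arg	ACG	I	elongator	argQZYV-serV	argQZYV-serV	0
serV	Ser	GCU		elongator	argQZYV-serV	argQZYV-serV	0
argU	Arg	UCU	mnm5U	elongator	argU	argU	0
argW	Arg	CCU		elongator	argW	argW	0
argX	Arg	CCG		elongator	argX-hisR-leuT-proM	argX-hisR-leuT-proM	0
hisR	His	GUG	Q	elongator	argX-hisR-leuT-proM	argX-hisR-leuT-proM	0
leuT	Leu	CAG		elongator	argX-hisR-leuT-proM	argX-hisR-leuT-proM	0
proM	Pro	UGG	cmo5U	elongator	argX-hisR-leuT-proM	argX-hisR-leuT-proM	0
asnT	Asn	GUU	Q	elongator	asnT	asnT	0
asnU	Asn	GUU	Q	elongator	asnU	asnU	0
asnV	Asn	GUU	Q	elongator	asnV	asnV	0
asnW	Asn	GUU	Q	elongator	asnW	asnW	0
aspV	Asp	GUC	Q	elongator	aspV	aspV	0
glyU	Gly	CCC		elongator	glyU	glyU	0
glyV	Gly	GCC		elongator	glyVXY	glyVXY	0
glyX	Gly	GCC		elongator	glyVXY	glyVXY	0
glyY	Gly	GCC		elongator	glyVXY	glyVXY	0
glyW	Gly	GCC		elongator	glyW-cysT-leuZ	glyW-cysT-leuZ	0
cysT	Cys	GCA		elongator	glyW-cysT-leuZ	glyW-cysT-leuZ	0
leuZ	Leu	UAA		elongator	glyW-cysT-leuZ	glyW-cysT-leuZ	0
ileX	Ile	CAU	k2C	elongator	ileX	ileX	0
ileY	Ile	CAU	k2C	elongator	ileY	ileY	0
leuU	Leu	GAG		elongator	leuU	leuU	0
leuV	Leu	CAG		elongator	leuVPQ	leuVPQ	0
leuP	Leu	CAG		elongator	leuVPQ	leuVPQ	0
leuQ	Leu	CAG		elongator	leuVPQ	leuVPQ	0
leuX	Leu	CAA		elongator	leuX	leuX	0
lysT	Lys	UUU	mnm5U	elongator	lysT-valT-lysW-valZ-lysYZQ	lysT-valT-lysW-valZ-lysYZQ	0
valT	Val	UAC	cmo5U	elongator	lysT-valT-lysW-valZ-lysYZQ	lysT-valT-lysW-valZ-lysYZQ	0
lysW	Lys	UUU	mnm5U	elongator	lysT-valT-lysW-valZ-lysYZQ	lysT-valT-lysW-valZ-lysYZQ	0
valZ	Val	UAC	cmo5U	elongator	lysT-valT-lysW-valZ-lysYZQ	lysT-valT-lysW-valZ-lysYZQ	0
lysY	Lys	UUU	mnm5U	elongator	lysT-valT-lysW-valZ-lysYZQ	lysT-valT-lysW-valZ-lysYZQ	0
lysZ	Lys	UUU	mnm5U	elongator	lysT-valT-lysW-valZ-lysYZQ	lysT-valT-lysW-valZ-lysYZQ	0
lysQ	Lys	UUU	mnm5U	elongator	lysT-valT-lysW-valZ-lysYZQ	lysT-valT-lysW-valZ-lysYZQ	0
metT	Met	CAU	ac4C	elongator	metT-leuW-glnUW-metU-glnVX	metT-leuW-glnUW-metU-glnVX	0
leuW	Leu	UAG	cmo5U	elongator	metT-leuW-glnUW-metU-glnVX	metT-leuW-glnUW-metU-glnVX	0
glnU	Gln	UUG	mnm5U	elongator	metT-leuW-glnUW-metU-glnVX	metT-leuW-glnUW-metU-glnVX	0
glnW	Gln	UUG	mnm5U	elongator	metT-leuW-glnUW-metU-glnVX	metT-leuW-glnUW-metU-glnVX	0
metU	Met	CAU	ac4C	elongator	metT-leuW-glnUW-metU-glnVX	metT-leuW-glnUW-metU-glnVX	0
glnV	Gln	CUG		elongator	metT-leuW-glnUW-metU-glnVX	metT-leuW-glnUW-metU-glnVX	0
glnX	Gln	CUG		elongator	metT-leuW-glnUW-metU-glnVX	metT-leuW-glnUW-metU-glnVX	0
metY	Met	CAU		initiator	metY	metY	0
metZ	Met	CAU		initiator	metZWV	metZWV	0
metW	Met	CAU		initiator	metZWV	metZWV	0
metV	Met	CAU		initiator	metZWV	metZWV	0
pheU	Phe	GAA		elongator	pheU	pheU	0
pheV	Phe	GAA		elongator	pheV	pheV	0
proK	Pro	CGG		elongator	proK	proK	0
proL	Pro	GGG		elongator	proL	proL	0
ileT	Ile	GAU		elongator	rrnA	ileT-alaT (rrnA)	1
alaT	Ala	UGC	cmo5U	elongator	rrnA	ileT-alaT (rrnA)	1
gltT	Glu	UUC	mnm5U	elongator	rrnB	gltT (rrnB)	1
gltU	Glu	UUC	mnm5U	elongator	rrnC	gltU-aspT-trpT (rrnC)	1
aspT	Asp	GUC	Q	elongator	rrnC	gltU-aspT-trpT (rrnC)	1
trpT	Trp	CCA		elongator	rrnC	gltU-aspT-trpT (rrnC)	1
ileU	Ile	GAU		elongator	rrnD	ileU-alaU-thrV (rrnD)	1
alaU	Ala	UGC	cmo5U	elongator	rrnD	ileU-alaU-thrV (rrnD)	1
thrV	Thr	GGU		elongator	rrnD	ileU-alaU-thrV (rrnD)	1
gltV	Glu	UUC	mnm5U	elongator	rrnE	gltV (rrnE)	1
gltW	Glu	UUC	mnm5U	elongator	rrnG	gltW (rrnG)	1
ileV	Ile	GAU		elongator	rrnH	ileV-alaV-aspU (rrnH)	1
alaV	Ala	UGC	cmo5U	elongator	rrnH	ileV-alaV-aspU (rrnH)	1
aspU	Asp	GUC	Q	elongator	rrnH	ileV-alaV-aspU (rrnH)	1
selC	Sec	UCA		selenocysteine	selC	selC	0
serT	Ser	UGA	cmo5U	elongator	serT	serT	0
serU	Ser	CGA		elongator	serU	serU	0
serW	Ser	GGA		elongator	serW	serW	0
serX	Ser	GGA		elongator	serX	serX	0
thrU	Thr	UGU	cmo5U	elongator	thrU-tyrU-glyT-thrT	thrU-tyrU-glyT-thrT	0
tyrU	Tyr	GUA	Q	elongator	thrU-tyrU-glyT-thrT	thrU-tyrU-glyT-thrT	0
glyT	Gly	UCC	mnm5U	elongator	thrU-tyrU-glyT-thrT	thrU-tyrU-glyT-thrT	0
thrT	Thr	GGU		elongator	thrU-tyrU-glyT-thrT	thrU-tyrU-glyT-thrT	0
thrW	Thr	CGU		elongator	thrW	thrW	0
tyrT	Tyr	GUA	Q	elongator	tyrTV	tyrTV	0
tyrV	Tyr	GUA	Q	elongator	tyrTV	tyrTV	0
valU	Val	UAC	cmo5U	elongator	valUXY-lysV	valUXY-lysV	0
valX	Val	UAC	cmo5U	elongator	valUXY-lysV	valUXY-lysV	0
valY	Val	UAC	cmo5U	elongator	valUXY-lysV	valUXY-lysV	0
lysV	Lys	UUU	mnm5U	elongator	valUXY-lysV	valUXY-lysV	0
valV	Val	GAC		elongator	valVW	valVW	0
valW	Val	GAC		elongator	valVW	valVW	0
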