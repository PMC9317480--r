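gene	category	SsSm	SsPl
flgB	flagellum.basal_body	PRESENT	PRESENT
flgC	flagellum.basal_body	PSEUDOGENE	PRESENT
flgF	flagellum.basal_body	PSEUDOGENE	PRESENT
flgG	flagellum.basal_body	PSEUDOGENE	PRESENT
flgH	flagellum.basal_body	PRESENT	PRESENT
fliE	flagellum.basal_body	PRESENT	PRESENT
fliM	flagellum.basal_body	PRESENT	PRESENT
fliN	flagellum.basal_body	PRESENT	PRESENT
fliI	flagellum.export	PRESENT	PRESENT
flgE	flagellum.hook	PSEUDOGENE	PRESENT
flgK	flagellum.hook	PSEUDOGENE	PRESENT
flgL	flagellum.filament	ABSENT	PRESENT
fliC	flagellum.filament	ABSENT	PRESENT
entA	siderophore.ent	ABSENT	ABSENT
entB	siderophore.ent	PSEUDOGENE	PSEUDOGENE
entC	siderophore.ent	ABSENT	ABSENT
entE	siderophore.ent	PSEUDOGENE	ABSENT
entF	siderophore.ent	ABSENT	PSEUDOGENE
irp1	siderophore.ybt	PRESENT	PRESENT
irp2	siderophore.ybt	PRESENT	PRESENT
fyuA	siderophore.ybt	PRESENT	PRESENT
ybtA	siderophore.ybt	PRESENT	PRESENT
ybtS	siderophore.ybt	ABSENT	ABSENT
ybtU	siderophore.ybt	ABSENT	ABSENT
ybtT	siderophore.ybt	ABSENT	ABSENT
ybtD	siderophore.ybt	ABSENT	ABSENT
psn	siderophore.ybt	ABSENT	ABSENT
fdeC	t5ss	PRESENT	PRESENT
invA	t5ss	PRESENT	ABSENT
sinH	t5ss	PRESENT	ABSENT
yopJ	toxin	PRESENT	PRESENT
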