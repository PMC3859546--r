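id	p15459	p15476	p15484	p15509	p15512	published_hpg	date_from_bce	date_to_bce
OY003-1	T	.	A	.	.	A	1800	1700
OY018-1	T	.	A	.	.	A	1800	1700
OY020-1	T	.	A	.	.	A	1800	1700
OY024-1	T	.	A	.	.	A	1800	1700
OY025-1	T	.	A	.	.	A	1800	1700
OY065-2	T	.	A	.	.	A	1800	1700
OY010-1	.	.	.	.	.	B	1800	1700
OY042-2	.	.	.	.	.	B	1800	1700
OY027-1	T	.	A	.	.	A	1800	1600
OY134-2	.	.	.	.	.	B	1800	1600
OY086-2	.	.	.	.	.	B	1800	1600
OY130-2	.	.	.	.	.	B	1800	1600
OY044-2	.	.	.	G	.	C	1800	1600
OY133-2	T	.	A	.	.	A	1600	1200
OY105-2	.	.	.	.	.	B	1600	1200
OY067-2	.	.	.	.	.	B	1600	1200
OY070-2	T	.	A	.	.	A	1200	900
OY061-2	T	.	A	.	.	A	1200	900
OY059-2	.	C	.	G	.	E	1200	900
OY090-2	T	.	A	.	.	A	1200	330
OY123-2	.	.	.	.	.	B	1200	330
OY072-2	.	.	.	.	.	B	1200	330
OY019-2	.	.	.	G	.	C	900	700
OY078-2	T	.	A	.	.	A	700	330
OY082-2	T	.	A	.	.	A	700	330
OY110-2	T	.	A	.	.	A	700	330
OY025-2	T	.	A	.	.	A	700	330
OY142-2	T	T	A	A	T	A	700	330
OY089-2	.	.	.	.	.	B	700	330
OY091-2	.	.	.	.	.	B	700	330
OY081-2	.	.	.	.	.	B	700	330
OY138-2	.	.	.	.	.	B	700	330
OY021-2	.	.	.	.	.	B	330	30
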