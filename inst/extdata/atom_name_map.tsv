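raw	canonical	combine
H	HN	single
HN	HN	single
N	N	single
C	CO	single
CO	CO	single
CA	CA	single
CB	CB	single
HA	HA	single
HA2	HA	mean
HA3	HA	mean
HB	HB	single
HB2	HB	mean
HB3	HB	mean
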