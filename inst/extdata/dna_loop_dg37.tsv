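type	size	dg
hairpin	3	3.5
hairpin	4	3.5
hairpin	5	3.3
hairpin	6	4.0
hairpin	7	4.2
hairpin	8	4.3
hairpin	9	4.5
hairpin	10	4.4
hairpin	12	4.7
hairpin	14	5.0
hairpin	16	5.2
hairpin	18	5.4
hairpin	20	5.6
hairpin	25	5.9
hairpin	30	6.3
bulge	1	4.0
bulge	2	2.9
bulge	3	3.1
bulge	4	3.2
bulge	5	3.3
bulge	6	3.5
bulge	7	3.7
bulge	8	3.9
bulge	9	4.0
bulge	10	4.1
bulge	12	4.3
bulge	14	4.5
bulge	16	4.7
bulge	18	4.9
bulge	20	5.1
bulge	25	5.3
bulge	30	5.5
internal	2	3.2
internal	3	3.2
internal	4	3.6
internal	5	4.0
internal	6	4.4
internal	7	4.6
internal	8	4.8
internal	9	4.9
internal	10	4.9
internal	12	5.2
internal	14	5.4
internal	16	5.6
internal	18	5.8
internal	20	5.9
internal	25	6.3
internal	30	6.6
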