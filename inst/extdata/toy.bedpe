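chr1	99999	100000	chr1	199999	200000	toy	0	+	+
chr1	100000	100001	chr1	200000	200001	toy	0	-	-
chr2	99999	100000	chr2	180000	180001	toy	0	+	-
chr3	99999	100000	chr3	199999	200000	toy	0	+	+
chr3	100000	100001	chr3	299999	300000	toy	0	-	+
chr3	200000	200001	chr3	300000	300001	toy	0	-	-
chr4	99999	100000	chr5	99999	100000	toy	0	+	+
chr4	100000	100001	chr5	100000	100001	toy	0	-	-
chr6	99999	100000	chr6	199999	200000	toy	0	+	+
chr6	100000	100001	chr6	200000	200001	toy	0	-	-
chr4	499999	500000	chr6	499999	500000	toy	0	+	+
chr4	500000	500001	chr6	500000	500001	toy	0	-	-
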