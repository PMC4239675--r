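sample	chrom	start	end	value
toy	chr1	1	1000000	2
toy	chr2	1	100000	2
toy	chr2	100001	180000	1
toy	chr2	180001	1000000	2
toy	chr3	1	1000000	2
toy	chr4	1	1000000	2
toy	chr5	1	1000000	2
toy	chr6	1	1000000	2
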