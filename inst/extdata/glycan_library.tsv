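key	class	antennae	bisected	galactoses	note
H5N2	oligomannose	0	0	0	Man5
H6N2	oligomannose	0	0	0	Man6
H7N2	oligomannose	0	0	0	Man7
H8N2	oligomannose	0	0	0	Man8
H9N2	oligomannose	0	0	0	Man9
H5N3	hybrid	1	0	0	hybrid
H5N3F1	hybrid	1	0	0	hybrid, core fucose
H6N3	hybrid	1	0	0	hybrid
H5N3S1	hybrid	1	0	0	hybrid, monosialyl
H6N3S1	hybrid	1	0	0	hybrid, monosialyl
H3N3	complex	1	0	0	monoantennary agalacto
H3N3F1	complex	1	0	0	monoantennary agalacto, fucosyl
H3N4	complex	2	0	0	biantennary agalacto
H3N4F1	complex	2	0	0	biantennary agalacto, fucosyl
H3N5	complex	2	1	0	biantennary agalacto, bisected
H3N5F1	complex	2	1	0	biantennary agalacto, bisected, fucosyl
H4N4	complex	2	0	1	biantennary monogalacto
H4N4F1	complex	2	0	1	biantennary monogalacto, fucosyl
H4N5	complex	2	1	1	biantennary monogalacto, bisected
H4N5F1	complex	2	1	1	biantennary monogalacto, bisected, fucosyl
H5N4	complex	2	0	2	biantennary digalacto
H5N4F1	complex	2	0	2	biantennary digalacto, fucosyl
H5N5	complex	2	1	2	biantennary digalacto, bisected
H5N5F1	complex	2	1	2	biantennary digalacto, bisected, fucosyl
H4N3S1	complex	1	0	1	monoantennary monosialyl
H4N4S1	complex	2	0	1	biantennary monosialyl
H5N4S1	complex	2	0	2	biantennary monosialyl
H5N4S1F1	complex	2	0	2	biantennary monosialyl, fucosyl
H5N5S1	complex	2	1	2	biantennary monosialyl, bisected
H5N5S1F1	complex	2	1	2	biantennary monosialyl, bisected, fucosyl
H5N4S2	complex	2	0	2	biantennary disialyl
H5N4S2F1	complex	2	0	2	biantennary disialyl, fucosyl
H5N5S2	complex	2	1	2	biantennary disialyl, bisected
H5N5S2F1	complex	2	1	2	biantennary disialyl, bisected, fucosyl
H6N5S2	complex	3	0	3	triantennary disialyl
H6N5S2F1	complex	3	0	3	triantennary disialyl, fucosyl
H6N5S3	complex	3	0	3	triantennary trisialyl
H6N5S3F1	complex	3	0	3	triantennary trisialyl, fucosyl
H7N6S3	complex	4	0	4	tetraantennary trisialyl
H7N6S3F1	complex	4	0	4	tetraantennary trisialyl, fucosyl
H7N6S4	complex	4	0	4	tetraantennary tetrasialyl
H7N6S4F1	complex	4	0	4	tetraantennary tetrasialyl, fucosyl
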