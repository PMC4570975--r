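# 5x7 block glyphs used by the text renderer.  Each record: a line with the
# character, then seven lines of five cells, '#' = on, '.' = off.  'I' is
# left-right symmetric by design (its mirror image is itself).

S
.###.
#...#
#....
.###.
....#
#...#
.###.

C
.###.
#...#
#....
#....
#....
#...#
.###.

I
.###.
..#..
..#..
..#..
..#..
..#..
.###.

E
#####
#....
#....
####.
#....
#....
#####

N
#...#
##..#
##..#
#.#.#
#..##
#..##
#...#
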