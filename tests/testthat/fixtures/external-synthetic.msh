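$MeshFormat
4.1 0 8
$EndMeshFormat
$PhysicalNames
6
1 1 "INLET"
1 2 "OUTLET"
1 3 "WALL_VESSEL"
1 4 "WALL_SAC"
2 5 "LUMEN"
2 6 "SAC"
$EndPhysicalNames
$Entities
0 4 2 0
1 0 0 0 0 1 0 1 1 0
2 2 0 0 2 1 0 1 2 0
3 0 0 0 2 1 0 1 3 0
4 1 1 0 2 1 0 1 4 0
1 0 0 0 1 1 0 1 5 0
2 1 0 0 2 1 0 1 6 0
$EndEntities
$Nodes
2 6 11 16
2 1 0 3
11
12
13
0 0 0
1 0 0
2 0 0
2 2 0 3
14
15
16
0 1 0
1 1 0
2 1 0
$EndNodes
$Elements
6 10 1 10
1 1 1 1
1 14 11
1 2 1 1
2 13 16
1 3 1 3
3 11 12
4 12 13
5 15 14
1 4 1 1
6 16 15
2 1 2 2
7 11 12 15
8 11 15 14
2 2 2 2
9 12 13 16
10 12 16 15
$EndElements
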