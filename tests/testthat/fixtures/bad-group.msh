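$MeshFormat
4.1 0 8
$EndMeshFormat
$PhysicalNames
3
1 1 "INLET"
1 2 "FREE_SURFACE"
2 3 "LUMEN"
$EndPhysicalNames
$Entities
0 2 1 0
1 0 0 0 0 1 0 1 1 0
2 2 0 0 2 1 0 1 2 0
1 0 0 0 1 1 0 1 3 0
$EndEntities
$Nodes
1 3 1 3
2 1 0 3
1
2
3
0 0 0
1 0 0
0 1 0
$EndNodes
$Elements
2 3 1 3
1 1 1 1
1 3 1
1 2 1 1
2 2 3
2 1 2 1
3 1 2 3
$EndElements
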