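format-version: 1.2
data-version: synthetic/seed-42

[Term]
id: GO:0000001
name: synthetic process root
namespace: biological_process

[Term]
id: GO:0000002
name: block 1 process
namespace: biological_process
is_a: GO:0000001

[Term]
id: GO:0000003
name: block 1 sub-process 1
namespace: biological_process
is_a: GO:0000002

[Term]
id: GO:0000004
name: block 1.1 term 1
namespace: biological_process
is_a: GO:0000003

[Term]
id: GO:0000005
name: block 1.1 term 2
namespace: biological_process
is_a: GO:0000003

[Term]
id: GO:0000006
name: block 1.1 term 3
namespace: biological_process
is_a: GO:0000003

[Term]
id: GO:0000007
name: block 1.1 term 4
namespace: biological_process
is_a: GO:0000003

[Term]
id: GO:0000008
name: block 1.1 term 5
namespace: biological_process
is_a: GO:0000003

[Term]
id: GO:0000009
name: block 1 sub-process 2
namespace: biological_process
is_a: GO:0000002

[Term]
id: GO:0000010
name: block 1.2 term 1
namespace: biological_process
is_a: GO:0000009

[Term]
id: GO:0000011
name: block 1.2 term 2
namespace: biological_process
is_a: GO:0000009

[Term]
id: GO:0000012
name: block 1.2 term 3
namespace: biological_process
is_a: GO:0000009

[Term]
id: GO:0000013
name: block 1.2 term 4
namespace: biological_process
is_a: GO:0000009

[Term]
id: GO:0000014
name: block 1.2 term 5
namespace: biological_process
is_a: GO:0000009

[Term]
id: GO:0000015
name: block 1 broad process
namespace: biological_process
is_a: GO:0000002

[Term]
id: GO:0000016
name: block 2 process
namespace: biological_process
is_a: GO:0000001

[Term]
id: GO:0000017
name: block 2 sub-process 1
namespace: biological_process
is_a: GO:0000016

[Term]
id: GO:0000018
name: block 2.1 term 1
namespace: biological_process
is_a: GO:0000017

[Term]
id: GO:0000019
name: block 2.1 term 2
namespace: biological_process
is_a: GO:0000017

[Term]
id: GO:0000020
name: block 2.1 term 3
namespace: biological_process
is_a: GO:0000017

[Term]
id: GO:0000021
name: block 2.1 term 4
namespace: biological_process
is_a: GO:0000017

[Term]
id: GO:0000022
name: block 2.1 term 5
namespace: biological_process
is_a: GO:0000017

[Term]
id: GO:0000023
name: block 2 sub-process 2
namespace: biological_process
is_a: GO:0000016

[Term]
id: GO:0000024
name: block 2.2 term 1
namespace: biological_process
is_a: GO:0000023

[Term]
id: GO:0000025
name: block 2.2 term 2
namespace: biological_process
is_a: GO:0000023

[Term]
id: GO:0000026
name: block 2.2 term 3
namespace: biological_process
is_a: GO:0000023

[Term]
id: GO:0000027
name: block 2.2 term 4
namespace: biological_process
is_a: GO:0000023

[Term]
id: GO:0000028
name: block 2.2 term 5
namespace: biological_process
is_a: GO:0000023

[Term]
id: GO:0000029
name: block 2 broad process
namespace: biological_process
is_a: GO:0000016
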