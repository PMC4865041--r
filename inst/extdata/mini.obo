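format-version: 1.2
ontology: mini-go

[Term]
id: GO:0008150
name: biological_process
namespace: biological_process

[Term]
id: GO:0100001
name: signaling
namespace: biological_process
is_a: GO:0008150 ! biological_process

[Term]
id: GO:0100002
name: cell surface receptor signaling
namespace: biological_process
alt_id: GO:0999999
is_a: GO:0100001 ! signaling

[Term]
id: GO:0003674
name: molecular_function
namespace: molecular_function

[Term]
id: GO:0100101
name: binding
namespace: molecular_function
is_a: GO:0003674 ! molecular_function
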