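{"type":"pan","dx":-400,"dy":-200}
{"type":"zoom","scale":2,"focal_x":512,"focal_y":384}
{"type":"pan","dx":300,"dy":0}
{"type":"begin_annotation","kind":"circle"}
{"type":"edit_annotation","dx":-40,"dy":20,"dw":30,"dh":0}
{"type":"commit_annotation","label":"Region 1"}
{"type":"pan_zoom","dx":-250,"dy":150,"scale":0.8,"focal_x":512,"focal_y":384}
{"type":"pan","dx":600,"dy":-300}
{"type":"begin_annotation","kind":"rectangle"}
{"type":"edit_annotation","dx":60,"dy":-30,"dw":40,"dh":20}
{"type":"commit_annotation","label":"Region 2"}
{"type":"zoom","scale":0.5,"focal_x":512,"focal_y":384}
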