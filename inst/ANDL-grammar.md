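# ANDL dialect emitted by `write_andl()` / parsed by `read_andl()`

One stochastic-Petri-net block per file. Whitespace at line boundaries is
ignored; lines starting with `//` are comments.

```
file        := "spn" "[" name "]" "{" places transitions "}"
places      := "places:" place-line+
place-line  := place-id "=" marking ";"        # marking 1 for C0, 0 otherwise
transitions := "transitions:" trans-line+
trans-line  := trans-id [" immediate"] ":" place-id "->" place-id ":" weight ";"
place-id    := "C" integer                     # C0 is the auxiliary start place
trans-id    := identifier                      # i<k> immediate, t<k> ordinary
weight      := number                          # firing weight; arc weights are
                                               # implicitly 1 on both arcs
```

Every transition has exactly one pre-place and one post-place (state-machine
class); immediate transitions must have pre-place `C0`. The single token sits
on `C0` in the initial marking. `read_andl(write_andl(net))` reproduces the
net structurally (places; pre/post/immediate/weight per transition).
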