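# Life-science vocabulary registry snapshot (namespace level).
# Lines ending in / or # are namespaces; other lines are term IRIs.
http://edamontology.org/
http://purl.obolibrary.org/obo/
https://bioschemas.org/
http://semanticscience.org/resource/
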