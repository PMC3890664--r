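tip,taxon
tacnae_h1,tacnae
tacnae_h2,tacnae
Cusco_h1,Cusco
Cusco_h2,Cusco
Ancash_h1,Ancash
Ancash_h2,Ancash
walkeri_h1,walkeri
walkeri_h2,walkeri
Ayacucho_h1,Ayacucho
Ayacucho_h2,Ayacucho
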