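((tacnae_h1,tacnae_h2)0.99,((Cusco_h1,Cusco_h2)0.99,((Ancash_h1,Ancash_h2)0.99,((walkeri_h1,walkeri_h2)0.99,(Ayacucho_h1,Ayacucho_h2)0.99)0.99)0.5)0.9)0.9;
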