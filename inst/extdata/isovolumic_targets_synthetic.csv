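V,Pes,Ped
12,110.0299508,-0.001796888358
16,147.4133072,0.0437876136
20,180.5950383,2.194961816
24,208.8466597,11.13762321
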