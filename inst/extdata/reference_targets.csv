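name,value,units
lv_pulse_pressure,119,mmHg
mean_lv_pressure,66,mmHg
p_ao_at_valve_open,115,mmHg
p_ao_at_valve_close,121,mmHg
mean_ventricular_volume,20.8,ml
stroke_volume,11.7,ml
rv_pulse_pressure,45.8,mmHg
mean_rv_pressure,22.9,mmHg
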