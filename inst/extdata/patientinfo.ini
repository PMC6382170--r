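# Patient information for PET SUV/SUL scaling.
PatientWeight = 75          ; kg
PatientHeight = 180         ; cm
PatientSex = M
InjectedActivity = 245e6    ; Bq at injection time
InjectionTime = 2019-01-01 10:00:00
ScanStartTime = 2019-01-01 11:25:00
HalfLife = 6586.2           ; s (F-18)
ActivityDecayCorrected = 0
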