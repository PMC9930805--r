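table,sex,group,mean_ca,mean_da,md
demirjian_train,male,6.01-7.00,6.74,7.40,0.66
demirjian_train,female,6.01-7.00,6.76,7.17,0.41
nolla_train,male,6.01-7.00,6.74,6.81,0.07
demirjian_test,total,total,10.62,10.83,0.21
nolla_test,total,total,10.62,10.18,-0.44
new_test,total,total,10.62,10.62,0.00
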