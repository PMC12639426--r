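# Nutritional composition of the 5 test staple foods, g per 100 g cooked
# (ready-to-eat). Letter codes follow the test-diet labels A-E.
food_code,food_name,protein,fat,total_carbohydrate,dietary_fiber,available_carbohydrate
A,refined rice,2.80,0.2,35.4,0.378,35.0
B,brown rice,2.89,1.0,31.7,2.830,28.9
C,germ rice,2.38,0.5,29.1,0.474,28.6
D,rice noodles,5.24,0.5,28.6,3.350,25.3
E,pasta,3.69,0.4,29.6,1.540,28.1
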